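#' Save and load fitted models as JSON
#'
#' Flat JSON serialisation for [qsar_pls()] fits and single [init_network()]
#' / [train_lm()] networks: scaling parameters, weights, loadings or biases,
#' and architecture — everything needed to reproduce predictions exactly.
#'
#' @param model a `qsar_pls` or `mlp_model` object.
#' @param path output file.
#' @return `write_model_json` invisibly returns `path`; `read_model_json`
#'   returns the reconstructed model.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "qsar_pls")) {
    doc <- list(type = "qsar_pls", n_lv = model$n_lv,
                coefficients = as.list(model$coefficients),
                intercept = model$intercept,
                x_weights = model$x_weights,
                x_loadings = model$x_loadings,
                y_loadings = model$y_loadings,
                scaling = model$scaling)
  } else if (inherits(model, "mlp_model")) {
    doc <- list(type = "mlp_model", n_inputs = model$n_inputs,
                n_hidden = model$n_hidden, w_ih = model$w_ih,
                b_1 = model$b_1, w_ho = model$w_ho, b_2 = model$b_2,
                scaling = model$scaling,
                activation = list(hidden = "tanh", output = "identity"))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "qsar_pls")) {
    structure(list(
      coefficients = unlist(doc$coefficients),
      intercept = doc$intercept,
      x_weights = as.matrix(doc$x_weights),
      x_loadings = as.matrix(doc$x_loadings),
      y_loadings = doc$y_loadings,
      n_lv = doc$n_lv,
      scaling = restore_scaling(doc$scaling),
      cv = NULL, data = NULL
    ), class = "qsar_pls")
  } else if (identical(doc$type, "mlp_model")) {
    sc <- if (is.null(doc$scaling)) NULL else {
      list(x = list(lo = unlist(doc$scaling$x$lo),
                    hi = unlist(doc$scaling$x$hi)),
           y = list(lo = unlist(doc$scaling$y$lo),
                    hi = unlist(doc$scaling$y$hi)))
    }
    structure(list(
      w_ih = as.matrix(doc$w_ih), b_1 = unlist(doc$b_1),
      w_ho = unlist(doc$w_ho), b_2 = doc$b_2,
      n_inputs = as.integer(doc$n_inputs),
      n_hidden = as.integer(doc$n_hidden),
      scaling = sc
    ), class = "mlp_model")
  } else {
    stop("unknown model type in ", path, call. = FALSE)
  }
}

restore_scaling <- function(sc) {
  list(x = list(mean = unlist(sc$x$mean), sd = unlist(sc$x$sd)),
       y = list(mean = sc$y$mean, sd = sc$y$sd))
}
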