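compound,phase,mechanism,step,reaction,dh298
genistein,gas,overall,1,ROH + PO. -> RO. + POH,5.6
genistein,water,overall,1,ROH + PO. -> RO. + POH,0.8
quercetin,gas,overall,1,ROH + PO. -> RO. + POH,-3.1
quercetin,water,overall,1,ROH + PO. -> RO. + POH,-5.6
genistein,gas,HAT,1,ROH -> RO. + H.,83.8
genistein,gas,HAT,2,PO. + H. -> POH,-78.2
genistein,water,HAT,1,ROH -> RO. + H.,85.3
genistein,water,HAT,2,PO. + H. -> POH,-84.5
quercetin,gas,HAT,1,ROH -> RO. + H.,75.1
quercetin,gas,HAT,2,PO. + H. -> POH,-78.2
quercetin,water,HAT,1,ROH -> RO. + H.,78.9
quercetin,water,HAT,2,PO. + H. -> POH,-84.5
genistein,gas,SPLET,1,ROH + PO. -> RO- + POH.+,134.2
genistein,gas,SPLET,2,RO- + POH.+ -> RO. + POH,-128.6
genistein,water,SPLET,1,ROH + PO. -> RO- + POH.+,32.9
genistein,water,SPLET,2,RO- + POH.+ -> RO. + POH,-32.1
quercetin,gas,SPLET,1,ROH + PO. -> RO- + POH.+,126.8
quercetin,gas,SPLET,2,RO- + POH.+ -> RO. + POH,-129.8
quercetin,water,SPLET,1,ROH + PO. -> RO- + POH.+,31.9
quercetin,water,SPLET,2,RO- + POH.+ -> RO. + POH,-37.5
genistein,gas,SETPL,1,ROH + PO. -> ROH.+ + PO-,144.6
genistein,gas,SETPL,2,ROH.+ + PO- -> RO. + POH,-138.9
genistein,water,SETPL,1,ROH + PO. -> ROH.+ + PO-,32.6
genistein,water,SETPL,2,ROH.+ + PO- -> RO. + POH,-31.7
quercetin,gas,SETPL,1,ROH + PO. -> ROH.+ + PO-,137.6
quercetin,gas,SETPL,2,ROH.+ + PO- -> RO. + POH,-140.7
quercetin,water,SETPL,1,ROH + PO. -> ROH.+ + PO-,28.0
quercetin,water,SETPL,2,ROH.+ + PO- -> RO. + POH,-33.6
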