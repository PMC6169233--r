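parent,metabolite,mw_parent,mw_metabolite,excretion_fraction
naphthalene,2-naphthol,128.17,144.17,0.066
fluorene,2-hydroxyfluorene,166.22,182.22,0.10
phenanthrene,3-hydroxyphenanthrene,178.23,194.23,0.05
pyrene,1-hydroxypyrene,202.25,218.25,0.20
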