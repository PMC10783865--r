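"allele","pseudo","epitope","assay","label"
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","WGEPVLWK","BA",0.172770926915109
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","RLAEYIFPMYF","MS",0
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","RIPSMMHW","BA",0.880516879516654
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","HWLYGLVYP","MS",0
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","AFAFSTVHIC","BA",0.116415693936869
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","DGIIRHHC","MS",1
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","LARRYFTME","BA",0.146829286473803
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","QMMWLPNC","MS",0
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","LGNLISCTWPD","BA",0.55987805245677
"SYN-01","GRADYPPATHYWLKRGYNDNKGKWPWETWGCSIN","EDDHMCLWF","MS",0
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","KHAVIDAH","BA",0.0453419661149383
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","KQYKCASKYGQ","MS",1
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","NEKNSYRNGN","BA",0.771092409756966
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","EVTIQPHDMWG","MS",1
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","CEMCEFLAWQ","BA",0.20846248716116
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","REGHTRKFPA","MS",0
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","HNNWGADWCS","BA",0.203641919977963
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","VESNQHRTKN","MS",1
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","HGICPDYFN","BA",0.101829930651002
"SYN-02","MQRAFWWRFAPPPQFFWAILKVIGMSKMATWENW","ERINGRKWNAL","MS",0
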