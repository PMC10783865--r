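"cdr3b","epitope","pseudo","label"
"DWLTVIKYREQLMHLFII","HGGDKFYKC","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"KTPQHYNHLQHWCIGW","PMYHLNEEV","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"QRNLMAPSIHNWFGSDVQRPHNRSK","MHWAGWMWC","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",1
"KRRNEKFYREWHCADCAN","VYPDKFLAW","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",1
"LNSKDMREFP","RYFERYVAS","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"QFGIIHQGIIIPYREITADWFTWIDSG","PSMDKFPHD","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"GNDRHFYREVEQDMGH","VYPDKFLAW","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",1
"AWIKDMTFHP","IIRERYNNW","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",1
"FDLTPILKENNHLDCARAIGHWQH","YIFHLNRNG","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"YCSIELEFWKKWFGERSLIIRCAIC","CDWAGWPAH","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"WPHEIKDMQPPIVP","IIRERYNNW","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",1
"SWENHLPRES","TMEHLNNQH","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",1
"PFIMQCPICVYYHYDDNHTI","YGLDKFCEF","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"VQCYQGSPWAR","HWLERYCDM","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"RDYMHMGCITSREVLKSINHCYAGFFMF","LARDKFWCS","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"FQIAERWKHW","RYFERYVAS","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"GRHQHHNRLQSEHDIASYTAWYHNEGS","AFAHLNNRE","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",0
"DNGEDWSSSGHSEI","HGGDKFYKC","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"VFVVDVHPRDGMGMHLVDENLRYMGH","RYFERYVAS","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"INFHYLWSIHRFCN","FRIERYTIQ","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",0
"KWECTEKDWIEWKMVEW","VYPDKFLAW","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",0
"EWYQYRCDCLYNLGFDSD","PVLDKFYGV","YTTFWLAHAIFRPRGKMMSAWSQCTVNDSKTEPH",0
"WAPGLVKLLMKKCYY","WFEERYASK","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
"VPICVDIVMCYGAYGF","YGLDKFCEF","AEIPQAIFSELHLYNFPIYNHSVNLVRSEKMCTY",0
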