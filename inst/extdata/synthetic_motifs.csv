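"seq_id","cluster","motif","start"
"tcr000002","cluster07","WQRE",3
"tcr000003","cluster01","GQGA",12
"tcr000005","cluster08","HEIY",10
"tcr000010","cluster02","YNEQ",16
"tcr000011","cluster08","HEIY",12
"tcr000012","cluster06","MVSD",5
"tcr000013","cluster07","WQRE",2
"tcr000016","cluster07","WQRE",6
"tcr000017","cluster06","MVSD",4
"tcr000018","cluster05","TFKA",9
"tcr000019","cluster02","YNEQ",18
"tcr000020","cluster02","YNEQ",3
"tcr000022","cluster08","HEIY",3
"tcr000023","cluster06","MVSD",8
"tcr000024","cluster02","YNEQ",6
"tcr000025","cluster06","MVSD",5
"tcr000026","cluster07","WQRE",9
"tcr000027","cluster07","WQRE",2
"tcr000028","cluster06","MVSD",8
"tcr000029","cluster06","MVSD",3
"tcr000030","cluster02","YNEQ",3
"tcr000031","cluster08","HEIY",13
"tcr000032","cluster05","TFKA",5
"tcr000034","cluster08","HEIY",9
"tcr000035","cluster05","TFKA",9
"tcr000036","cluster06","MVSD",8
"tcr000039","cluster06","MVSD",8
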