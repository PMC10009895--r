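allele	expressed_vehicle	expressed_ifng
HLA-A*11:01:01	FALSE	FALSE
HLA-A*24:02:01	TRUE	TRUE
HLA-B*35:08:01	TRUE	TRUE
HLA-B*55:01:01	TRUE	TRUE
HLA-C*01:02:01	TRUE	TRUE
HLA-C*04:01:01	TRUE	TRUE
HLA-DRA*01:01:01	TRUE	TRUE
HLA-DRA*01:02:02	TRUE	TRUE
HLA-DRB1*11:04:01	TRUE	TRUE
HLA-DRB1*13:03:01	TRUE	TRUE
HLA-DRB3*01:01:02	FALSE	TRUE
HLA-DRB3*02:02:01	FALSE	TRUE
HLA-DQA1*05:05:01	FALSE	FALSE
HLA-DQB1*03:01:01	TRUE	TRUE
HLA-DPA1*01:03:01	FALSE	TRUE
HLA-DPB1*04:01:01	FALSE	TRUE
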