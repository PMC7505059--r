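category,total,incountry,duplicated,banked_total
overall,2885,493,425,560
endemic,1264,168,144,197
useful,674,310,NA,341
threatened,249,25,17,25
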