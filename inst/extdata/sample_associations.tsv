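disease	mirna
Alopecia	hsa-mir-106b
Alopecia	hsa-mir-125b-1
Alopecia	hsa-mir-125b-2
Alopecia	hsa-mir-221
Alopecia	hsa-mir-410
Alopecia	hsa-mir-203
Alopecia	hsa-mir-575
Alopecia	hsa-mir-602
Alopecia	hsa-mir-106a
Alopecia	hsa-mir-125b
Acute Brucellosis	hsa-mir-126
Acute Brucellosis	hsa-mir-4753
Cataract	hsa-mir-184
Cataract	hsa-mir-125b
Cataract	hsa-mir-589
Cataract	hsa-mir-326
Cataract	hsa-mir-675
Cataract	hsa-mir-34a
Cataract	hsa-mir-15a
Carcinoma, Embryonal	hsa-mir-372
Carcinoma, Embryonal	hsa-mir-373
Carcinoma, Embryonal	hsa-mir-29c
Carcinoma, Embryonal	hsa-mir-19
Carcinoma, Embryonal	hsa-mir-29c
Carcinoma, Embryonal	hsa-mir-134
Carcinoma, Embryonal	hsa-mir-140
Carcinoma, Embryonal	hsa-mir-302b
Carcinoma, Embryonal	hsa-mir-27
Carcinoma, Embryonal	hsa-mir-34a
Carcinoma, Embryonal	hsa-mir-601
Pancreatic Diseases	hsa-let-7b
Pancreatic Diseases	hsa-mir-495
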