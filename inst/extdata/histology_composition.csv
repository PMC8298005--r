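label,subtype,weight
malignant,invasive ductal carcinoma,65
malignant,invasive lobular carcinoma,7
malignant,ductal carcinoma in situ,7
malignant,adenocarcinoma,3
malignant,poorly differentiated carcinoma,2
malignant,mucinous mammary carcinoma,1
benign,fibroadenoma,44
benign,fibrocystic changes,33
benign,sclerosing adenosis,6
benign,benign without atypia,17
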