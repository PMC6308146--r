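{
  "F_RMS": "first-order root mean squared",
  "F_MAD": "first-order mean absolute deviation",
  "F_rMAD": "first-order robust mean absolute deviation",
  "F_IQR": "first-order interquartile range",
  "F_SD": "first-order standard deviation",
  "F_P10": "first-order 10th percentile",
  "F_P90": "first-order 90th percentile",
  "glcm_CT": "GLCM cluster tendency",
  "glcm_CP": "GLCM cluster prominence",
  "glcm_CS": "GLCM cluster shade",
  "glcm_IMC": "GLCM informational measure of correlation 1",
  "glcm_IMC2": "GLCM informational measure of correlation 2",
  "glcm_IDM": "GLCM inverse difference moment",
  "glcm_IDMN": "GLCM inverse difference moment normalized",
  "glcm_ID": "GLCM inverse difference",
  "glcm_IDN": "GLCM inverse difference normalized",
  "glrlm_SRE": "GLRLM short run emphasis",
  "glrlm_LRE": "GLRLM long run emphasis",
  "glrlm_GLN": "GLRLM gray level non-uniformity",
  "glrlm_GLNN": "GLRLM gray level non-uniformity normalized",
  "glrlm_GLV": "GLRLM gray level variance",
  "glrlm_HGLRE": "GLRLM high gray level run emphasis",
  "glrlm_LRHGLE": "GLRLM long run high gray level emphasis",
  "glrlm_LRLGLE": "GLRLM long run low gray level emphasis",
  "glrlm_LGLRE": "GLRLM low gray level run emphasis",
  "glrlm_RE": "GLRLM run entropy",
  "glrlm_RLN": "GLRLM run length non-uniformity",
  "glrlm_RLNN": "GLRLM run length non-uniformity normalized",
  "glrlm_RP": "GLRLM run percentage",
  "glrlm_RV": "GLRLM run variance",
  "glrlm_SRHGLE": "GLRLM short run high gray level emphasis",
  "glrlm_SRLGLE": "GLRLM short run low gray level emphasis",
  "glszm_SAE": "GLSZM small area emphasis",
  "glszm_LAE": "GLSZM large area emphasis",
  "glszm_GLN": "GLSZM gray level non-uniformity",
  "glszm_GLNN": "GLSZM gray level non-uniformity normalized",
  "glszm_GLV": "GLSZM gray level variance",
  "glszm_HGLZE": "GLSZM high gray level zone emphasis",
  "glszm_LAHGLE": "GLSZM large area high gray level emphasis",
  "glszm_LALGLE": "GLSZM large area low gray level emphasis",
  "glszm_LGLZE": "GLSZM low gray level zone emphasis",
  "glszm_ZE": "GLSZM zone entropy",
  "glszm_SZN": "GLSZM size zone non-uniformity",
  "glszm_SZNN": "GLSZM size zone non-uniformity normalized",
  "glszm_ZP": "GLSZM zone percentage",
  "glszm_ZV": "GLSZM zone variance",
  "glszm_SAHGLE": "GLSZM small area high gray level emphasis",
  "glszm_SALGLE": "GLSZM small area low gray level emphasis",
  "gldm_SDE": "GLDM small dependence emphasis",
  "gldm_LDE": "GLDM large dependence emphasis",
  "gldm_GLN": "GLDM gray level non-uniformity",
  "gldm_DN": "GLDM dependence non-uniformity",
  "gldm_DNN": "GLDM dependence non-uniformity normalized",
  "gldm_GLV": "GLDM gray level variance",
  "gldm_DV": "GLDM dependence variance",
  "gldm_DE": "GLDM dependence entropy",
  "gldm_LGLE": "GLDM low gray level emphasis",
  "gldm_HGLE": "GLDM high gray level emphasis",
  "gldm_SDLGLE": "GLDM small dependence low gray level emphasis",
  "gldm_SDHGLE": "GLDM small dependence high gray level emphasis",
  "gldm_LDLGLE": "GLDM large dependence low gray level emphasis",
  "gldm_LDHGLE": "GLDM large dependence high gray level emphasis"
}
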