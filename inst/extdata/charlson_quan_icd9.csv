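category,weight,pattern
myocardial_infarction,1,410
myocardial_infarction,1,412
congestive_heart_failure,1,398.91
congestive_heart_failure,1,402.01
congestive_heart_failure,1,402.11
congestive_heart_failure,1,402.91
congestive_heart_failure,1,404.01
congestive_heart_failure,1,404.03
congestive_heart_failure,1,404.11
congestive_heart_failure,1,404.13
congestive_heart_failure,1,404.91
congestive_heart_failure,1,404.93
congestive_heart_failure,1,425.4
congestive_heart_failure,1,425.5
congestive_heart_failure,1,425.6
congestive_heart_failure,1,425.7
congestive_heart_failure,1,425.8
congestive_heart_failure,1,425.9
congestive_heart_failure,1,428
peripheral_vascular,1,093.0
peripheral_vascular,1,437.3
peripheral_vascular,1,440
peripheral_vascular,1,441
peripheral_vascular,1,443.1
peripheral_vascular,1,443.2
peripheral_vascular,1,443.3
peripheral_vascular,1,443.4
peripheral_vascular,1,443.5
peripheral_vascular,1,443.6
peripheral_vascular,1,443.7
peripheral_vascular,1,443.8
peripheral_vascular,1,443.9
peripheral_vascular,1,447.1
peripheral_vascular,1,557.1
peripheral_vascular,1,557.9
cerebrovascular,1,362.34
cerebrovascular,1,430-438
dementia,1,290
dementia,1,294.1
dementia,1,331.2
chronic_pulmonary,1,416.8
chronic_pulmonary,1,416.9
chronic_pulmonary,1,490-505
chronic_pulmonary,1,506.4
chronic_pulmonary,1,508.1
chronic_pulmonary,1,508.8
rheumatic,1,446.5
rheumatic,1,710.0
rheumatic,1,710.1
rheumatic,1,710.2
rheumatic,1,710.3
rheumatic,1,710.4
rheumatic,1,714.0
rheumatic,1,714.1
rheumatic,1,714.2
rheumatic,1,714.8
rheumatic,1,725
peptic_ulcer,1,531-534
mild_liver,1,070.22
mild_liver,1,070.23
mild_liver,1,070.32
mild_liver,1,070.33
mild_liver,1,070.44
mild_liver,1,070.54
mild_liver,1,070.6
mild_liver,1,070.9
mild_liver,1,570
mild_liver,1,571
mild_liver,1,573.3
mild_liver,1,573.4
mild_liver,1,573.8
mild_liver,1,573.9
diabetes,1,250.0
diabetes,1,250.1
diabetes,1,250.2
diabetes,1,250.3
diabetes,1,250.8
diabetes,1,250.9
diabetes_complicated,2,250.4
diabetes_complicated,2,250.5
diabetes_complicated,2,250.6
diabetes_complicated,2,250.7
hemiplegia,2,334.1
hemiplegia,2,342
hemiplegia,2,343
hemiplegia,2,344.0
hemiplegia,2,344.1
hemiplegia,2,344.2
hemiplegia,2,344.3
hemiplegia,2,344.4
hemiplegia,2,344.5
hemiplegia,2,344.6
hemiplegia,2,344.9
renal,2,403.01
renal,2,403.11
renal,2,403.91
renal,2,404.02
renal,2,404.12
renal,2,404.92
renal,2,582
renal,2,583.0
renal,2,583.1
renal,2,583.2
renal,2,583.3
renal,2,583.4
renal,2,583.5
renal,2,583.6
renal,2,583.7
renal,2,585
renal,2,586
renal,2,588.0
malignancy,2,140-172
malignancy,2,174-195
malignancy,2,200-208
malignancy,2,238.6
severe_liver,3,456.0
severe_liver,3,456.1
severe_liver,3,456.2
severe_liver,3,572.2
severe_liver,3,572.3
severe_liver,3,572.4
severe_liver,3,572.5
severe_liver,3,572.6
severe_liver,3,572.7
severe_liver,3,572.8
metastatic,6,196-199
aids,6,042-044
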