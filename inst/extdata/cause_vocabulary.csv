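code,label,is_cancer,site_group
ca_bladder,Bladder Cancer,TRUE,Bladder
ca_breast,Breast Cancer,TRUE,"Breast, All"
ca_brain,Brain/Other Nervous System Cancer,TRUE,Brain/Other Nervous System
ca_cervix,Cervical Cancer,TRUE,Cervix
ca_colorectal,Colon/Rectum Cancer,TRUE,Colon/Rectum
ca_esophagus,Esophageal Cancer,TRUE,Esophagus
ca_kidney,Kidney Cancer,TRUE,Kidney
ca_larynx,Laryngeal Cancer,TRUE,Larynx
ca_leukemia,Leukemia,TRUE,Leukemia
ca_liver,Liver/Intrahepatic Bile Duct Cancer,TRUE,Liver/Intrahepatic Bile Duct
ca_lung,Lung Cancer,TRUE,"Lung, All"
ca_lymphoma,Lymphoma,TRUE,Lymphoma
ca_melanoma,Melanoma,TRUE,Melanoma
ca_myeloma,Myeloma,TRUE,Myeloma
ca_oral,Oral Cavity/Pharynx Cancer,TRUE,Oral Cavity/Pharynx
ca_ovary,Ovarian Cancer,TRUE,Ovary
ca_pancreas,Pancreatic Cancer,TRUE,Pancreas
ca_prostate,Prostate Cancer,TRUE,Prostate
ca_stomach,Stomach Cancer,TRUE,Stomach
ca_thyroid,Thyroid Cancer,TRUE,Thyroid
ca_uterus,Uterine Cancer,TRUE,Uterus
ca_other,Other Cancer,TRUE,Other Types
nc_tuberculosis,Tuberculosis,FALSE,
nc_syphilis,Syphilis,FALSE,
nc_other_infectious,Other Infectious and Parasitic Diseases,FALSE,
nc_septicemia,Septicemia,FALSE,
nc_diabetes,Diabetes Mellitus,FALSE,
nc_alzheimer,Alzheimer Disease,FALSE,
nc_heart,Diseases of Heart,FALSE,
nc_hypertension,Hypertension without Heart Disease,FALSE,
nc_cerebrovascular,Cerebrovascular Diseases,FALSE,
nc_atherosclerosis,Atherosclerosis,FALSE,
nc_aortic_aneurysm,Aortic Aneurysm and Dissection,FALSE,
nc_other_arteries,"Other Diseases of Arteries, Arterioles, Capillaries",FALSE,
nc_pneumonia_influenza,Pneumonia and Influenza,FALSE,
nc_copd,Chronic Obstructive Pulmonary Disease,FALSE,
nc_ulcer,Stomach and Duodenal Ulcers,FALSE,
nc_liver_disease,Chronic Liver Disease and Cirrhosis,FALSE,
nc_nephritis,"Nephritis, Nephrotic Syndrome and Nephrosis",FALSE,
nc_pregnancy,"Complications of Pregnancy, Childbirth, Puerperium",FALSE,
nc_congenital,Congenital Anomalies,FALSE,
nc_perinatal,Certain Conditions Originating in Perinatal Period,FALSE,
nc_ill_defined,"Symptoms, Signs and Ill-Defined Conditions",FALSE,
nc_accidents,Accidents and Adverse Effects,FALSE,
nc_suicide,Suicide and Self-Inflicted Injury,FALSE,
nc_homicide,Homicide and Legal Intervention,FALSE,
nc_benign_neoplasm,"In Situ, Benign or Unknown Behavior Neoplasm",FALSE,
nc_other,Other Cause of Death,FALSE,
cod_unknown,Unknown or Missing Cause of Death,NA,
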