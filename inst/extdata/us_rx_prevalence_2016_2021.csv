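grouping_variable,category,n_rx,pct_indic_narrow,pct_indic_broad,pct_contraindicated,pct_indic_not_contra
all,all,1655101,56.5,75.09,54.34,32.92
sex,male,697174,56.72,75.17,53.14,33.73
sex,female,957927,56.33,75.03,55.2,32.33
education,missing,11158,54.48,72.52,40.9,40.95
education,0-11 years,333066,55.22,74.92,54.46,32.55
education,12 years,517288,56.15,75.12,56.03,31.45
education,13+ years,107486,56.03,75.25,56.71,32.01
education,18+ years,666574,57.52,75.18,53.3,33.9
age_group,0-17,39628,56.43,73.6,20.03,58.11
age_group,18-44,278849,54.3,71.31,46.02,37.76
age_group,45-64,702388,56.85,75.49,55.53,32.48
age_group,65-84,568400,57.5,76.79,58.46,30.13
age_group,85 or older,60475,52.92,72.3,57.27,29.11
race,White,1256808,56.22,74.86,54.45,32.83
race,Black,272257,57.62,75.79,54.85,32.18
race,American Indian-Alaska,15348,51.88,74.71,58.18,29.91
race,Asian,51263,61.82,77.7,46.35,39.98
race,Multiple,59425,54.09,74.7,55.33,32.91
year,2016,288469,56.72,72.76,47.37,37.42
year,2017,291290,54.29,71.15,46.86,36.83
year,2018,297588,54.51,75.61,57.55,30.54
year,2019,265693,55.73,76.41,59.44,29.58
year,2020,251225,57.9,77.06,58.73,30.46
year,2021,260836,60.36,77.97,56.68,32.42
approval_year_group,1941-1978,424017,42.13,66.95,64.56,20.96
approval_year_group,1979-1991,381966,67.09,83.78,55.67,35.42
approval_year_group,1992-1997,431967,60.58,76.57,53.79,33.64
approval_year_group,1998-2018,388135,57.23,73.78,42.46,42.71
medicare,Medicare,534965,56.72,76.07,58.61,29.92
medicare,No Medicare,1091120,56.39,74.61,52.24,34.38
medicaid,Medicaid,279757,54.11,74.99,52.76,34.06
medicaid,No Medicaid,1346328,56.99,75.11,54.66,32.68
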