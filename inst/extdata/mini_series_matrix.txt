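!Series_title	"Miniature expression series for parser tests"
!Series_platform_id	"GPL0000"
!Sample_geo_accession	"GSM0001"	"GSM0002"	"GSM0003"	"GSM0004"	"GSM0005"	"GSM0006"	"GSM0007"
!Sample_characteristics_ch1	"tissue: lymph node"	"tissue: lymph node"	"tissue: lymph node"	"tissue: lymph node"	"tissue: lymph node"	"tissue: lymph node"	"tissue: lymph node"
!Sample_characteristics_ch1	"subtype: ABC"	"subtype: ABC"	"subtype: GCB"	"subtype: GCB"	"subtype: GCB"	"subtype: ABC"	"subtype: UNC"
!series_matrix_table_begin
"ID_REF"	"GSM0001"	"GSM0002"	"GSM0003"	"GSM0004"	"GSM0005"	"GSM0006"	"GSM0007"
"P001"	5.12	4.98	6.01	5.77	6.12	5.05	5.50
"P002"	7.40	7.31	6.88	6.92	7.01	7.55	7.10
"P003"	3.25	3.40	3.10	3.05	3.33	3.21	3.18
"P004"	8.88	9.01	8.75	8.69	8.91	9.12	8.80
"P005"	4.44	4.51	4.38	4.29	4.47	4.60	4.40
!series_matrix_table_end
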