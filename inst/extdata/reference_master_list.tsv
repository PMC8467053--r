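# reference master peak list reported by the original FFPE xenograft MALDI-MSI study
# columns: nominal m/z, whole-dataset CV (%), accurate m/z (FT-ICR), putative ID,
# adduct, ftic_detected (detected on FT-ICR), tier (accurate-mass identification
# tier), theoretical_only (assignment not observed experimentally)
mz	cv_percent	accurate_mz	id	adduct	ftic_detected	tier	theoretical_only
534.6	41	NA	n.i.	NA	FALSE	none	FALSE
548.6	50	NA	n.i.	NA	FALSE	none	FALSE
562.6	45	NA	n.i.	NA	FALSE	none	FALSE
576.7	9	NA	n.i.	NA	FALSE	none	FALSE
604.7	50	NA	n.i.	NA	FALSE	none	FALSE
609.4	14	609.340	PI 20:1	[M+H-H2O]+	TRUE	sub_ppm	TRUE
639.5	32	639.408	PA 32:5	[M+H]+	TRUE	8_10_ppm	TRUE
683.5	22	683.434	PG 31:4	[M+H-H2O]+	TRUE	8_10_ppm	TRUE
707.6	23	NA	n.i.	NA	FALSE	none	FALSE
722.5	21	NA	n.i.	NA	FALSE	none	FALSE
727.6	16	727.460	PG 33:5	[M+H]+	TRUE	8_10_ppm	TRUE
740.6	31	740.520	PE 34:1	[M+Na]+	TRUE	sub_ppm	FALSE
758.6	23	NA	n.i.	NA	FALSE	none	FALSE
766.6	29	766.536	PE 36:2	[M+Na]+	TRUE	sub_ppm	FALSE
768.6	33	768.554	PE 38:4	[M+H]+	TRUE	sub_ppm	FALSE
771.6	8	771.486	PA 40:6	[M+Na]+	TRUE	8_10_ppm	TRUE
779.3	18	779.254	n.i.	NA	TRUE	none	FALSE
784.6	23	NA	n.i.	NA	FALSE	none	FALSE
786.6	23	NA	n.i.	NA	FALSE	none	FALSE
788.6	28	788.5201	PE 38:5	[M+Na]+	TRUE	sub_ppm	FALSE
790.6	32	790.536	PE 38:4	[M+Na]+	TRUE	sub_ppm	FALSE
801.2	16	801.193	n.i.	NA	TRUE	none	FALSE
812.6	32	812.541	PS 36:1	[M+Na]+	TRUE	sub_ppm	FALSE
815.6	14	NA	n.i.	NA	FALSE	none	FALSE
826.6	8	NA	n.i.	NA	FALSE	none	FALSE
867.2	30	867.088	n.i.	NA	TRUE	none	FALSE
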