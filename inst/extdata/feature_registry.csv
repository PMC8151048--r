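name,family,ibsi_name,fallback
stat_mean,intensity,Mean intensity,none
stat_var,intensity,Intensity variance (population),none
stat_skew,intensity,Intensity skewness,0 on constant ROI
stat_kurt,intensity,Excess intensity kurtosis,0 on constant ROI
stat_median,intensity,Median intensity,none
stat_min,intensity,Minimum intensity,none
stat_max,intensity,Maximum intensity,none
stat_p10,intensity,10th intensity percentile,none
stat_p90,intensity,90th intensity percentile,none
stat_iqr,intensity,Interquartile range,none
stat_range,intensity,Intensity range,none
stat_mad,intensity,Mean absolute deviation,none
stat_rmad,intensity,Robust mean absolute deviation (P10-P90),none
stat_medad,intensity,Median absolute deviation,none
stat_cov,intensity,Coefficient of variation,0 when mean is 0
stat_qcod,intensity,Quartile coefficient of dispersion,0 when P25+P75 is 0
stat_energy,intensity,Energy,none
stat_rms,intensity,Root mean square intensity,none
hist_mean,intensity_histogram,Intensity histogram mean,none
hist_var,intensity_histogram,Intensity histogram variance,none
hist_skew,intensity_histogram,Intensity histogram skewness,0 on single grey level
hist_kurt,intensity_histogram,Intensity histogram excess kurtosis,0 on single grey level
hist_median,intensity_histogram,Intensity histogram median,none
hist_mode,intensity_histogram,Intensity histogram mode,smallest level on ties
hist_min_grade,intensity_histogram,Minimum histogram grade,none
hist_max_grade,intensity_histogram,Maximum histogram grade,none
hist_entropy,intensity_histogram,Intensity histogram entropy (log2),none
hist_uniformity,intensity_histogram,Intensity histogram uniformity / histogram energy,none
hist_auc_csh,intensity_histogram,Area under cumulative intensity-volume histogram,1 on zero-dose ROI
cooc_joint_max,glcm,Joint maximum,point-mass matrix on degenerate ROI
cooc_joint_avg,glcm,Joint average,point-mass matrix on degenerate ROI
cooc_joint_var,glcm,Joint variance,point-mass matrix on degenerate ROI
cooc_joint_entropy,glcm,Joint entropy,point-mass matrix on degenerate ROI
cooc_diff_avg,glcm,Difference average,point-mass matrix on degenerate ROI
cooc_diff_var,glcm,Difference variance,point-mass matrix on degenerate ROI
cooc_diff_entropy,glcm,Difference entropy,point-mass matrix on degenerate ROI
cooc_sum_avg,glcm,Sum average,point-mass matrix on degenerate ROI
cooc_sum_var,glcm,Sum variance,point-mass matrix on degenerate ROI
cooc_sum_entropy,glcm,Sum entropy,point-mass matrix on degenerate ROI
cooc_energy,glcm,Angular second moment (energy),point-mass matrix on degenerate ROI
cooc_contrast,glcm,Contrast,point-mass matrix on degenerate ROI
cooc_dissimilarity,glcm,Dissimilarity,point-mass matrix on degenerate ROI
cooc_inv_diff,glcm,Inverse difference,point-mass matrix on degenerate ROI
cooc_inv_diff_norm,glcm,Inverse difference normalized,point-mass matrix on degenerate ROI
cooc_inv_diff_mom,glcm,Inverse difference moment,point-mass matrix on degenerate ROI
cooc_inv_diff_mom_norm,glcm,Inverse difference moment normalized,point-mass matrix on degenerate ROI
cooc_inv_var,glcm,Inverse variance,point-mass matrix on degenerate ROI
cooc_correlation,glcm,Correlation,1 when joint variance is 0
cooc_autocorr,glcm,Autocorrelation,point-mass matrix on degenerate ROI
cooc_cluster_tendency,glcm,Cluster tendency,point-mass matrix on degenerate ROI
cooc_cluster_shade,glcm,Cluster shade,point-mass matrix on degenerate ROI
cooc_cluster_prominence,glcm,Cluster prominence,point-mass matrix on degenerate ROI
cooc_info_corr1,glcm,Information correlation 1,0 when marginal entropy is 0
cooc_info_corr2,glcm,Information correlation 2,0 on single grey level
rlm_sre,glrlm,Short run emphasis,none
rlm_lre,glrlm,Long run emphasis,none
rlm_lgre,glrlm,Low grey level run emphasis,none
rlm_hgre,glrlm,High grey level run emphasis,none
rlm_srlge,glrlm,Short run low grey level emphasis,none
rlm_srhge,glrlm,Short run high grey level emphasis,none
rlm_lrlge,glrlm,Long run low grey level emphasis,none
rlm_lrhge,glrlm,Long run high grey level emphasis,none
rlm_glnu,glrlm,Grey level non-uniformity,none
rlm_glnu_norm,glrlm,Grey level non-uniformity normalized,none
rlm_rlnu,glrlm,Run length non-uniformity,none
rlm_rlnu_norm,glrlm,Run length non-uniformity normalized,none
rlm_run_pct,glrlm,Run percentage (per direction),none
rlm_gl_var,glrlm,Grey level variance (runs),none
rlm_rl_var,glrlm,Run length variance,none
rlm_run_entropy,glrlm,Run entropy (log2),none
szm_sze,glszm,Small zone emphasis,none
szm_lze,glszm,Large zone emphasis,none
szm_lgze,glszm,Low grey level zone emphasis,none
szm_hgze,glszm,High grey level zone emphasis,none
szm_szlge,glszm,Small zone low grey level emphasis,none
szm_szhge,glszm,Small zone high grey level emphasis,none
szm_lzlge,glszm,Large zone low grey level emphasis,none
szm_lzhge,glszm,Large zone high grey level emphasis,none
szm_glnu,glszm,Grey level non-uniformity (zones),none
szm_glnu_norm,glszm,Grey level non-uniformity normalized (zones),none
szm_zsnu,glszm,Zone size non-uniformity,none
szm_zsnu_norm,glszm,Zone size non-uniformity normalized,none
szm_zone_pct,glszm,Zone percentage,none
szm_gl_var,glszm,Grey level variance (zones),none
szm_zs_var,glszm,Zone size variance,none
szm_zone_entropy,glszm,Zone entropy (log2),none
ngt_coarseness,ngtdm,Coarseness,capped at 1e6 on uniform ROI
ngt_contrast,ngtdm,NGTDM contrast,0 on single grey level
ngt_busyness,ngtdm,Busyness,0 on single grey level
ngt_complexity,ngtdm,Complexity,0 on single grey level
ngt_strength,ngtdm,Strength,0 on single grey level
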