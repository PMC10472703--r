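comparison,age_weeks,unit,mean_ctrl,sem_ctrl,n_ctrl,mean_db,sem_db,n_db,t_reported,df_reported
op1_amplitude,25,uV,126.31,4.42,14,83.89,7.92,11,-4.939,23
op2_amplitude,25,uV,174.63,4.53,14,135.81,13.44,11,-3.008,23
sum_op_amplitude,25,uV,446.37,10.24,14,353.10,34.77,11,-2.847,23
op4_amplitude,9,uV,31.80,4.00,14,49.89,5.56,11,2.709,23
onl_thickness,25,um,65.78,2.72,7,53.60,2.02,6,-3.488,11
inl_thickness,25,um,44.40,1.93,7,30.85,1.55,6,-5.347,11
photoreceptor_density,25,cells_per_80um,428.32,33.82,7,316.41,14.35,6,-2.865,11
cone_count,25,cells_per_160um,49.41,3.58,7,28.76,4.10,6,-3.815,11
axon_terminals,25,count,134.21,12.13,7,55.75,8.75,6,-5.080,11
dendritic_boutons,25,count,45.88,3.87,7,14.69,1.91,5,-6.356,10
basal_respiration,25,pmol_per_min,122.76,7.93,5,75.29,6.75,7,-4.554,10
maximal_respiration,25,pmol_per_min,147.87,11.98,5,94.41,14.11,7,-2.725,10
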