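# Full task-based processing: blur for voxelwise analysis, percent-signal
# scaling, motion + outlier censoring, duration-modulated events.
subject_id sub001
blocks tshift volreg blur mask scale regress
epi epi_run1.nii.gz
anat anat.nii.gz
stim_times times_task.txt times_control.txt
stim_labels task control
tcat_remove_first_trs 4
blur_size 6
mask_epi_anat yes
regress_basis dmUBLOCK
regress_censor_motion 0.3
regress_censor_outliers 0.05
regress_motion_per_run yes
regress_reml ar1
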