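# Resting-state processing with physiological regressors.  Bandpassing to
# the low-frequency band is shown commented out: at TR = 2 s it costs 60%
# of the degrees of freedom, so it is not a default.
subject_id sub002
blocks despike ricor tshift volreg blur mask scale regress
epi epi_rest.nii.gz
anat anat.nii.gz
cardiac cardiac.1D
resp resp.1D
blur_size 6
regress_censor_motion 0.2
regress_censor_outliers 0.05
regress_apply_mot_types demean deriv
# regress_bandpass 0.01 0.1
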