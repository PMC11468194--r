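# Multi-echo resting state with optimal combination and sinc interpolation
# to minimise interpolation blurring (the combine block is implicit once
# echo_times lists more than one echo).
subject_id sub003
blocks tshift volreg mask scale regress
epi echo1.nii.gz echo2.nii.gz echo3.nii.gz
echo_times 12.5 27.6 42.7
anat anat.nii.gz
tshift_interp wsinc9
volreg_warp_final_interp wsinc5
combine_method OC
regress_censor_motion 0.2
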