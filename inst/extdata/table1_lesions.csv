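# Lesion-level imaging features of the TACE cohort: 26 HCC lesions in 16 patients.
# Columns:
#   patient_id            subject number (repeat lesions of one subject share the number)
#   lesion_location       hepatic segment / description as reported
#   size_mm               longest lesion diameter on conventional imaging, mm
#   visual_uptake         visual FLT uptake relative to background liver (verbatim)
#   background_suv_mean   SUV_mean of a 3-cm tumour-free liver ROI
#   suv60_mean_pre        baseline lesion SUV60_mean
#   suv60_max_pre         baseline lesion SUV60_max
#   mrecist               mRECIST response category (CR/PR/SD/PD) or NE
#   pct_change_mean       percent change in SUV60_mean after TACE, or NE
#   pct_change_max        percent change in SUV60_max after TACE, or NE
#   pfs_months            progression-free survival, months (blank where not reported per-lesion)
#   note                  reported footnote for the lesion/patient, if any
patient_id,lesion_location,size_mm,visual_uptake,background_suv_mean,suv60_mean_pre,suv60_max_pre,mrecist,pct_change_mean,pct_change_max,pfs_months,note
1,"Diffuse disease, R lobe",117,Isotense,4.3,3.4,5.1,PR,-12.2,13.9,3,
2,Segment V/VI,56,Hyperintense rim and hypointense center,4.9,4.3,7.8,PR,-55.5,-45.5,6.6,
3,Segment VII,60,Isotense,6.3,5.7,7.9,SD,-65.2,-42.6,5.3,
4,Segment VI,20,Isotense,5.5,2.8,5.5,SD,-6.0,-14.4,4.5,
4,Segment V,52,Isotense,5.5,4.1,5.8,SD,-0.9,-6.7,,
5,Segment II,44,Hyperintense,6.6,7.5,10.3,SD,-37.4,1.4,11.4,
5,Segment VI,24,Hyperintense,6.6,7.6,9.9,SD,10.9,-0.7,,untreated lesion
5,Segment IV,19,Hyperintense,6.6,7.3,9.8,SD,15.5,26.2,,
5,Segment IV,16,Hyperintense,6.6,7.8,10.3,SD,5.9,1.9,,
5,Segment VIII,15,Hyperintense,6.6,7.1,9.4,SD,0.07,0.9,,
5,Segment IV,13,Hyperintense,6.6,7.8,11.3,SD,-4.7,0.9,,
5,Segment VIII,19,Hyperintense,6.6,7.1,8.2,PR,22.2,36.5,,
6,Segment III,22,Hyperintense,4.8,7.6,10.2,NE,-69.2,-61.9,17.3,
7,Segment III,22,Hyperintense,6.1,10.9,14.3,NE,NE,NE,8.0,
8,Segment VIII,42,Hyperintense,6.5,7.8,11.5,PR,-66.4,-41.5,1.5,
9,Segment II,28,Hyperintense,6.3,7.9,10.3,CR,-58.6,-46.1,5.2,
10,Segment I,62,Hyperintense,7.7,8.1,20.4,PR,-71.3,-41.0,1.1,patient died of unrelated illness
11,Segment III,38,Hyperintense,6.1,7.1,10.6,PR,-29.0,-21.5,7.8,
12,Segment VIII,59,Mixed isotense and hypotense,8.0,5.1,10.9,PR,-55.8,-32.8,16.7,
12,Segment IV,60,Hypotense,8.0,2.9,8.4,PR,-51.6,-33.9,,photopenic lesion
13,Segment VI,31,Hyperintense,4.8,6.4,8.9,CR,-39.4,-48.6,19.1,
14,Segment VII (sagittal),18,Hyperintense,5.3,5.3,7.4,CR,-33.9,-30.5,8.1,
14,Segment VIII,26,Hyperintense,5.3,6.3,7.5,CR,-33.5,-39.1,,
14,Segment VII (medial),10,Hyperintense,5.3,6.6,8.0,SD,17.2,30.9,,
15,Segment VIII,34,Hyperintense,5.5,7.3,10.4,PR,-52.4,-46.3,8.9,
16,Segment VI/VII,73,Hyperintense,5.7,6.6,11.6,PR,-65.8,-24.1,14.5,patient underwent liver transplantation
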