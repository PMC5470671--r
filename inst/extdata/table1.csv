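dataset,id,gender,age,time_poststroke,hand_dominance,stroke_type,affected_hemisphere,mri_report,lesion_site,brunnstrom_proximal,brunnstrom_distal,fma_pre,fma_post,tempa_pre,tempa_post,wmft_pre,wmft_post,true_condition,prediction
training,1,M,72,15,R,I,L,brain stem,subcortical,3,3,23,37,-67,-46,26,37,F,
training,2,M,68,12,R,H,L,thalamus intracerebral,subcortical,4,4,38,50,-48,-33,49,56,F,
training,3,M,53,2,R,H,R,basal ganglion ICH,subcortical,3,2,13,26,-86,-78,31,38,F,
training,4,M,59,1,R,I,R,MCA,cortical,5,5,59,66,-14,-6,67,73,F,
training,5,M,50,5,R,H,L,basal ganglion ICH,subcortical,3,3,11,19,-72,-64,12,14,F,
training,6,M,65,8,R,I,L,post part of MCA,cortical,5,4,42,43,-44,-27,55,54,F,
training,7,M,59,12,R,I,L,MCA,cortical,5,4,35,42,-35,-40,46,43,F,
training,8,F,33,6,R,I,R,MCA,cortical,2,2,9,8,-93,-87,20,29,F,
training,9,M,69,3,R,H,L,thalamus,subcortical,5,6,42,53,-29,-20,64,66,F,
training,10,F,60,1,R,I,R,MCA,cortical,2,2,13,26,-93,-84,31,41,F,
training,11,M,62,13,R,I,L,basalganglia and thalamus,subcortical,3,2,15,17,-94,-76,35,36,F,
training,12,M,65,5,R,H,L,"ICH, pons and midbrain",subcortical,5,5,52,61,-76,-49,39,47,F,
training,13,F,75,4,R,I,R,MCA,cortical,4,5,36,52,-57,-29,43,57,F,
training,14,M,27,2,L,H,L,Fronto-temporal regions,cortical,3,2,17,21,-69,-79,12,23,F,
training,15,F,68,2,R,H,R,ICH thalamus,subcortical,4,5,31,40,-41,-35,54,61,F,
training,16,M,63,2,R,I,L,MCA,cortical,2,1,8,9,-75,-86,21,36,F,
training,17,M,57,2,R,H,L,putamen,subcortical,4,4,24,35,-64,-50,42,54,F,
training,18,M,69,1,R,H,L,thalamus,subcortical,5,6,43,52,-33,-17,56,60,F,
training,19,M,51,1,R,I,L,corona rediata,subcortical,4,2,22,31,-68,-54,42,49,F,
training,20,M,39,15,R,H,L,ICH,subcortical,3,3,22,26,-70,-68,38,38,P,
training,21,M,60,17,R,H,L,ICH putamen,subcortical,3,2,21,19,-79,-74,35,36,P,
training,22,F,38,5,R,H,L,ICH thalamus,subcortical,4,4,45,49,-35,-25,57,59,P,
training,23,M,58,4,R,I,R,MCA,cortical,5,5,35,40,-45,-36,50,55,P,
training,24,F,44,10,L,I,L,MCA,cortical,5,4,36,38,-51,-46,51,53,P,
training,25,M,64,12,R,H,R,thalamic and basal ganglia,subcortical,3,3,17,16,-93,-86,35,32,P,
training,26,F,61,3,R,I,R,Frontoparietal,cortical,4,4,36,42,-47,-39,48,52,P,
training,27,F,79,1,R,I,R,paramedian area of the pons,subcortical,5,5,43,44,-26,-27,65,59,P,
training,28,M,46,10,R,I,L,medulla,subcortical,5,5,43,44,-23,-28,62,65,P,
training,29,M,50,9,R,I,R,MCA,cortical,5,4,51,52,-22,-21,67,64,P,
training,30,M,28,9,L,H,L,Fronto-temporal regions,subcortical,3,3,23,24,-82,-68,42,45,P,
training,31,M,57,5,R,H,R,thalamus and brain stem ICH,subcortical,4,5,34,38,-65,-66,21,29,P,
training,32,F,75,5,R,H,R,ICH thalamus,subcortical,4,5,33,31,-50,-49,42,46,P,
training,33,M,54,4,R,I,L,ACA,cortical,5,5,55,57,-7,-7,68,68,P,
training,34,M,76,5,R,I,L,Posterior corona radiata,subcortical,3,5,31,25,-49,-43,50,57,P,
training,35,F,49,20,R,I,R,middle and superior frontal lobe,cortical,5,4,35,37,-51,-55,46,49,P,
training,36,M,58,12,R,H,R,"thalamus, corona radiata, lentinucleus",subcortical,2,1,10,10,-57,-69,12,21,P,
training,37,M,45,2,R,I,L,medulla,subcortical,5,5,42,44,-25,-26,63,65,P,
validation,1,F,59,7,R,H,R,MCA,cortical,2,4,23,25,-88,-88,36,49.5,F,P
validation,2,M,58,8,R,I,L,basalganglia and thalamus,subcortical,3,3,24,33,-105,-87,46,54,F,F
validation,3,M,44,21,R,I,R,basal ganglia,subcortical,2,2,14,16,-104,-87,43,28,F,F
validation,4,M,34,8,R,I,L,ganglion,subcortical,5,4,38,40,-81,-82,49,60,F,F
validation,5,M,46,8,R,H,R,basal ganglion,subcortical,3,3,18,29,-86,-93,50,59,F,F
validation,6,M,44,13,R,I,L,paramedian pontine,subcortical,4,5,50,56,-28,-7,68,71,F,F
validation,7,M,60,1,R,I,R,posterior limb of internal capsule,subcortical,5,5,52,59,-15,-5,73,71,F,F
validation,8,M,39,7,R,I,L,medial medulla and cerebellum,subcortical,5,4,38,39,-16,-14,72,83,F,F
validation,9,M,60,6,R,I,L,caudate nucleus,subcortical,3,4,30,32,-75,-57,50,51,F,F
validation,10,M,53,4,R,H,R,basal ganglion,subcortical,4,4,38,52,-63,-25,65,68,F,F
validation,11,M,51,12,R,H,L,MCA,subcortical,3,4,22,29,-82,-79,40,40,F,F
validation,12,F,27,7,R,I,R,basal ganglion,subcortical,4,5,33,34,-68,-65,46,45,P,P
validation,13,M,64,16,R,I,R,MCA,cortical,3,3,21,22,-63,-63,37,37,P,F
validation,14,M,55,5,R,I,R,mid brain to pons,subcortical,3,3,48,51,-60,-52,59,63,P,P
validation,15,M,62,10,R,I,L,MCA,cortical,4,4,46,47,-42,-68,74,74,P,P
validation,16,M,51,14,R,H,R,AVM; fronto-tempro-parietal,cortical,3,4,37,43,-44,-48,61,62,P,F
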