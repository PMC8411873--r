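cause,age_group,theta,theta_se,alpha,mu,nu,cf
ihd,25plus,0.2969,0.01787,1.9,12.0,40.2,2.4
stroke,25plus,0.2720,0.07697,6.2,16.7,23.7,2.4
copd,25plus,0.2510,0.06762,6.5,2.5,32.0,2.4
lc,25plus,0.2942,0.06147,6.2,9.3,29.8,2.4
lri,25plus,0.4468,0.11735,6.4,5.7,8.4,2.4
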