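experiment,measure,test,comparison,stat,value
exp1,target_error,anova,,F,3.40
exp1,target_error,anova,,eta_p_sq,0.14
exp1,target_error,anova,,cohens_f,0.40
exp1,target_error,anova,,p,0.042
exp1,target_error,anova,,bf,1.65
exp1,target_error,tukey,CBxdlPFC,p,0.46
exp1,target_error,tukey,CBxdlPFC,cohens_d,0.71
exp1,target_error,tukey,CBxdlPFC,hedges_g,0.68
exp1,target_error,tukey,CBxSHAM,p,0.32
exp1,target_error,tukey,CBxSHAM,cohens_d,0.44
exp1,target_error,tukey,CBxSHAM,hedges_g,0.43
exp1,target_error,tukey,dlPFCxSHAM,p,0.033
exp1,target_error,tukey,dlPFCxSHAM,cohens_d,0.85
exp1,target_error,tukey,dlPFCxSHAM,hedges_g,0.83
exp1,explicit,anova,,F,2.03
exp1,explicit,anova,,eta_p_sq,0.086
exp1,explicit,anova,,cohens_f,0.31
exp1,explicit,anova,,bf,0.66
exp1,explicit,ttest,CBxSHAM,t,0.27
exp1,explicit,ttest,CBxSHAM,p,0.79
exp1,explicit,ttest,CBxSHAM,cohens_d,0.10
exp1,explicit,ttest,CBxSHAM,hedges_g,0.10
exp1,explicit,ttest,dlPFCxSHAM,t,1.74
exp1,explicit,ttest,dlPFCxSHAM,p,0.09
exp1,explicit,ttest,dlPFCxSHAM,cohens_d,0.63
exp1,explicit,ttest,dlPFCxSHAM,hedges_g,0.62
exp1,implicit,anova,,F,0.82
exp1,implicit,anova,,eta_p_sq,0.037
exp1,implicit,anova,,cohens_f,0.20
exp1,implicit,anova,,bf,0.29
exp1,implicit,ttest,CBxSHAM,t,0.94
exp1,implicit,ttest,CBxSHAM,p,0.36
exp1,implicit,ttest,CBxSHAM,cohens_d,0.34
exp1,implicit,ttest,CBxSHAM,hedges_g,0.33
exp1,implicit,ttest,dlPFCxSHAM,t,-0.29
exp1,implicit,ttest,dlPFCxSHAM,p,0.77
exp1,implicit,ttest,dlPFCxSHAM,cohens_d,0.11
exp1,implicit,ttest,dlPFCxSHAM,hedges_g,0.10
exp2,target_error,anova,,F,1.55
exp2,target_error,anova,,eta_p_sq,0.11
exp2,target_error,anova,,cohens_f,0.35
exp2,target_error,anova,,bf,0.57
exp2,target_error,ttest,CBxSHAM,t,1.78
exp2,target_error,ttest,CBxSHAM,p,0.093
exp2,target_error,ttest,CBxSHAM,cohens_d,0.81
exp2,target_error,ttest,CBxSHAM,hedges_g,0.78
exp2,target_error,ttest,dlPFCxSHAM,t,0.76
exp2,target_error,ttest,dlPFCxSHAM,p,0.46
exp2,target_error,ttest,dlPFCxSHAM,cohens_d,0.35
exp2,target_error,ttest,dlPFCxSHAM,hedges_g,0.33
exp2,explicit,anova,,F,1.33
exp2,explicit,anova,,eta_p_sq,0.09
exp2,explicit,anova,,cohens_f,0.31
exp2,explicit,anova,,bf,0.50
exp2,explicit,ttest,CBxSHAM,t,-1.01
exp2,explicit,ttest,CBxSHAM,p,0.33
exp2,explicit,ttest,CBxSHAM,cohens_d,0.46
exp2,explicit,ttest,CBxSHAM,hedges_g,0.44
exp2,explicit,ttest,dlPFCxSHAM,t,0.39
exp2,explicit,ttest,dlPFCxSHAM,p,0.70
exp2,explicit,ttest,dlPFCxSHAM,cohens_d,0.18
exp2,explicit,ttest,dlPFCxSHAM,hedges_g,0.17
exp2,implicit,anova,,F,2.93
exp2,implicit,anova,,eta_p_sq,0.18
exp2,implicit,anova,,cohens_f,0.47
exp2,implicit,anova,,bf,1.31
exp2,implicit,ttest,CBxSHAM,t,1.84
exp2,implicit,ttest,CBxSHAM,p,0.083
exp2,implicit,ttest,CBxSHAM,cohens_d,0.84
exp2,implicit,ttest,CBxSHAM,hedges_g,0.81
exp2,implicit,ttest,dlPFCxSHAM,p,0.95
exp2,implicit,ttest,dlPFCxSHAM,cohens_d,0.03
exp2,implicit,ttest,dlPFCxSHAM,hedges_g,0.03
exp3a,target_error,ttest,HORxVER,t,2.66
exp3a,target_error,ttest,HORxVER,p,0.017
exp3a,target_error,ttest,HORxVER,cohens_d,1.26
exp3a,target_error,ttest,HORxVER,hedges_g,1.20
exp3a,explicit,ttest,HORxVER,t,1.50
exp3a,explicit,ttest,HORxVER,p,0.15
exp3a,explicit,ttest,HORxVER,cohens_d,0.71
exp3a,explicit,ttest,HORxVER,hedges_g,0.68
exp3a,implicit,ttest,HORxVER,t,-0.50
exp3a,implicit,ttest,HORxVER,p,0.62
exp3a,implicit,ttest,HORxVER,cohens_d,0.24
exp3a,implicit,ttest,HORxVER,hedges_g,0.23
exp3b,target_error,factorial,interaction,F,1.16
exp3b,target_error,factorial,interaction,eta_p_sq,0.04
exp3b,target_error,factorial,interaction,cohens_f,0.20
exp3b,target_error,factorial,context,F,8.34
exp3b,target_error,factorial,context,eta_p_sq,0.14
exp3b,target_error,factorial,context,cohens_f,0.40
exp3b,target_error,factorial,context,p,0.006
exp3b,target_error,factorial,stim,F,1.48
exp3b,target_error,factorial,stim,eta_p_sq,0.05
exp3b,target_error,factorial,stim,cohens_f,0.23
exp3b,explicit,factorial,interaction,F,1.51
exp3b,explicit,factorial,interaction,eta_p_sq,0.06
exp3b,explicit,factorial,interaction,cohens_f,0.25
exp3b,explicit,factorial,context,F,17.62
exp3b,explicit,factorial,context,eta_p_sq,0.25
exp3b,explicit,factorial,context,cohens_f,0.58
exp3b,explicit,factorial,stim,F,0.49
exp3b,explicit,factorial,stim,eta_p_sq,0.02
exp3b,explicit,factorial,stim,cohens_f,0.14
exp3b,implicit,factorial,interaction,F,2.68
exp3b,implicit,factorial,interaction,eta_p_sq,0.09
exp3b,implicit,factorial,interaction,cohens_f,0.31
exp3b,implicit,factorial,context,F,11.09
exp3b,implicit,factorial,context,eta_p_sq,0.18
exp3b,implicit,factorial,context,cohens_f,0.47
exp3b,implicit,factorial,stim,F,1.21
exp3b,implicit,factorial,stim,eta_p_sq,0.05
exp3b,implicit,factorial,stim,cohens_f,0.23
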