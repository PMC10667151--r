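parameter,muscle,median_long,median_short,delta_pct_published
t2init_ms,gastrocnemius,26.3,26.3,0.0
t2init_ms,soleus,25.1,25.5,1.6
is_down_e2,gastrocnemius,2.4,2.1,13.3
is_down_e2,soleus,3.7,3.7,0.0
miv_au,gastrocnemius,0.96,0.96,0.0
miv_au,soleus,0.94,0.94,0.0
hs_up_e2,gastrocnemius,37.9,25.0,41.0
hs_up_e2,soleus,78.3,42.3,59.7
tthp_s,gastrocnemius,15.8,9.8,46.9
tthp_s,soleus,12.9,9.2,33.5
ttp_s,gastrocnemius,31.7,27.7,13.5
ttp_s,soleus,28.8,29.1,1.0
hpv_au,gastrocnemius,1.04,1.02,1.9
hpv_au,soleus,1.08,1.06,1.9
tthr_s,gastrocnemius,60.4,91.7,41.2
tthr_s,soleus,78.8,136.5,53.6
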