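unit_id,member_publications,notes
dorr_1986,Dorr 1986,
skinner_ravikumar,Skinner 1989;Ravikumar 2000,Ravikumar 2000 reports the 13-year follow-up of the Skinner 1989 cohort; the two publications are one trial
baker_2006,Baker 2006,
keating_2006,Keating 2006,
blomfeldt_2007,Blomfeldt 2007,
macaulay_2008,Macaulay 2008,
mouzopoulos_2008,Mouzopoulos 2008,
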