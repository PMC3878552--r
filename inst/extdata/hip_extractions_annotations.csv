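review_id,study_unit_id,outcome_id,variable,label,adjudicated,rationale
BMJ,skinner_ravikumar,dislocation,arm_a_total,error,FALSE,denominators for the two arms transposed when entered into analysis software
BMJ,skinner_ravikumar,dislocation,arm_b_total,error,FALSE,denominators for the two arms transposed when entered into analysis software
BMJ,skinner_ravikumar,dislocation,arm_a_events,selection,TRUE,numerator recalculated from rounded percentages; equals the reference value but not a count reported by the primary publications
BMJ,skinner_ravikumar,dislocation,arm_b_events,selection,TRUE,numerator recalculated from rounded percentages; equals the reference value but not a count reported by the primary publications
BMJ,keating_2006,dislocation,arm_b_events,selection,FALSE,comparator events taken from a separate trial arm recruited under different eligibility criteria
BMJ,keating_2006,dislocation,arm_b_total,selection,FALSE,comparator denominator (n=111) from a separate trial arm recruited under different eligibility criteria
Cochrane,skinner_ravikumar,dislocation,arm_a_total,error,FALSE,review generated its own denominators after failing to identify the follow-up publication
Cochrane,skinner_ravikumar,dislocation,arm_b_total,error,FALSE,review generated its own denominators after failing to identify the follow-up publication
Cochrane,skinner_ravikumar,dislocation,arm_a_events,selection,FALSE,numerator recalculated from rounded percentages applied to self-generated denominators
Cochrane,skinner_ravikumar,dislocation,arm_b_events,selection,FALSE,numerator recalculated from rounded percentages applied to self-generated denominators
BMJ,dorr_1986,mortality_1y,arm_a_events,error,TRUE,primary publication reports 7 deaths without an arm split; review apportioned 3 and 4 to the arms
BMJ,dorr_1986,mortality_1y,arm_b_events,error,TRUE,primary publication reports 7 deaths without an arm split; review apportioned 3 and 4 to the arms
BMJ,dorr_1986,mortality_1y,arm_a_total,identical,TRUE,denominator matches the randomised arm size in the primary publication
BMJ,dorr_1986,mortality_1y,arm_b_total,identical,TRUE,denominator matches the randomised arm size in the primary publication
BMJ,skinner_ravikumar,mortality_1y,arm_a_total,error,FALSE,denominators for the two arms transposed
BMJ,skinner_ravikumar,mortality_1y,arm_b_total,error,FALSE,denominators for the two arms transposed
BMJ,skinner_ravikumar,mortality_1y,arm_a_events,selection,FALSE,numerator recalculated from rounded percentages and transposed denominators
BMJ,skinner_ravikumar,mortality_1y,arm_b_events,selection,FALSE,numerator recalculated from rounded percentages and transposed denominators
BMJ,keating_2006,mortality_1y,arm_b_events,selection,FALSE,comparator events taken from a separate trial arm
BMJ,keating_2006,mortality_1y,arm_b_total,selection,FALSE,comparator denominator (n=111) from a separate trial arm
BMJ,macaulay_2008,mortality_1y,arm_a_events,selection,TRUE,six-month deaths analysed as one-year data; other reviews omit this study from the one-year analysis
BMJ,macaulay_2008,mortality_1y,arm_b_events,selection,TRUE,six-month deaths analysed as one-year data; other reviews omit this study from the one-year analysis
BMJ,macaulay_2008,mortality_1y,arm_a_total,identical,TRUE,denominator matches the randomised arm size in the primary publication
BMJ,macaulay_2008,mortality_1y,arm_b_total,identical,TRUE,denominator matches the randomised arm size in the primary publication
BMJ,mouzopoulos_2008,mortality_1y,arm_a_events,selection,FALSE,revisions and exclusions counted as deaths without imputation
BMJ,mouzopoulos_2008,mortality_1y,arm_b_events,selection,FALSE,revisions and exclusions counted as deaths without imputation
BMJ,mouzopoulos_2008,mortality_1y,arm_a_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 4
BMJ,mouzopoulos_2008,mortality_1y,arm_b_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 5
Cochrane,skinner_ravikumar,mortality_1y,arm_a_total,error,FALSE,review generated its own denominators after failing to identify the follow-up publication
Cochrane,skinner_ravikumar,mortality_1y,arm_b_total,error,FALSE,review generated its own denominators after failing to identify the follow-up publication
Cochrane,skinner_ravikumar,mortality_1y,arm_a_events,selection,FALSE,numerator recalculated from rounded percentages applied to self-generated denominators
Cochrane,skinner_ravikumar,mortality_1y,arm_b_events,selection,FALSE,numerator recalculated from rounded percentages applied to self-generated denominators
Cochrane,mouzopoulos_2008,mortality_1y,arm_a_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 4
Cochrane,mouzopoulos_2008,mortality_1y,arm_b_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 5
BMJ,skinner_ravikumar,revision,arm_a_total,error,FALSE,denominators for the two arms transposed
BMJ,skinner_ravikumar,revision,arm_b_total,error,FALSE,denominators for the two arms transposed
BMJ,skinner_ravikumar,revision,arm_b_events,error,TRUE,numerator computed as 25 percent although the primary publication reports 24 percent; equals the reference value by coincidence of rounding
BMJ,blomfeldt_2007,revision,arm_a_events,selection,FALSE,re-operations on the contralateral side and for lower-limb trauma counted as revisions
BMJ,blomfeldt_2007,revision,arm_b_events,selection,FALSE,re-operations on the contralateral side and for lower-limb trauma counted as revisions
BMJ,mouzopoulos_2008,revision,arm_b_events,selection,FALSE,two comparator revisions excluded from the analysis
BMJ,mouzopoulos_2008,revision,arm_a_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 4
BMJ,mouzopoulos_2008,revision,arm_b_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 5
Cochrane,skinner_ravikumar,revision,arm_a_total,error,FALSE,review generated its own denominators after failing to identify the follow-up publication
Cochrane,skinner_ravikumar,revision,arm_b_total,error,FALSE,review generated its own denominators after failing to identify the follow-up publication
Cochrane,skinner_ravikumar,revision,arm_a_events,selection,FALSE,numerator recalculated from rounded percentages applied to self-generated denominators
Cochrane,skinner_ravikumar,revision,arm_b_events,selection,FALSE,numerator recalculated from rounded percentages applied to self-generated denominators
Cochrane,baker_2006,revision,arm_b_events,selection,FALSE,planned or awaiting revisions omitted; only completed revisions counted
Cochrane,blomfeldt_2007,revision,arm_a_events,selection,FALSE,a wound revision counted; reference counts implant revisions only
Cochrane,mouzopoulos_2008,revision,arm_a_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 4
Cochrane,mouzopoulos_2008,revision,arm_b_total,selection,FALSE,all randomised participants retained; reference applied an intention-to-treat exclusion of 5
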