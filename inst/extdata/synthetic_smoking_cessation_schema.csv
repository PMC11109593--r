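entity_id,name,kind,parent_id,value_unit,arm_scoped
bct_goal_setting,goal setting,presence_absence,,,TRUE
bct_problem_solving,problem solving,presence_absence,,,TRUE
bct_action_planning,action planning,presence_absence,,,TRUE
bct_review_goals,review of behavioural goals,presence_absence,,,TRUE
bct_feedback_on_behaviour,feedback on behaviour,presence_absence,,,TRUE
bct_self_monitoring,self monitoring,presence_absence,,,TRUE
bct_social_support,social support,presence_absence,,,TRUE
bct_instruction_on_behaviour,instruction on how to perform the behaviour,presence_absence,,,TRUE
bct_information_health_consequences,information about health consequences,presence_absence,,,TRUE
bct_demonstration,demonstration of the behaviour,presence_absence,,,TRUE
bct_behavioural_practice,behavioural practice and rehearsal,presence_absence,,,TRUE
bct_habit_formation,habit formation,presence_absence,,,TRUE
bct_graded_tasks,graded tasks,presence_absence,,,TRUE
bct_financial_incentive,financial incentives,presence_absence,,,TRUE
bct_reward_outcome,reward on outcome,presence_absence,,,TRUE
bct_pros_and_cons,weighing pros and cons,presence_absence,,,TRUE
bct_commitment,commitment,presence_absence,,,TRUE
bct_restructuring_physical_environment,restructuring the physical environment,presence_absence,,,TRUE
bct_avoidance_cues,avoidance of cues for smoking,presence_absence,,,TRUE
bct_distraction,distraction,presence_absence,,,TRUE
bct_reduce_negative_emotions,reducing negative emotions,presence_absence,,,TRUE
bct_pharmacological_support,pharmacological support,presence_absence,,,TRUE
rx_nrt_patch,nicotine replacement patch,presence_absence,,,TRUE
rx_nrt_gum,nicotine replacement gum,presence_absence,,,TRUE
rx_varenicline,varenicline,presence_absence,,,TRUE
rx_bupropion,bupropion,presence_absence,,,TRUE
rx_e_cigarette,electronic cigarette,presence_absence,,,TRUE
mode_face_to_face,face to face delivery,presence_absence,,,TRUE
mode_telephone,telephone delivery,presence_absence,,,TRUE
mode_text_messaging,text messaging delivery,presence_absence,,,TRUE
mode_internet,internet based delivery,presence_absence,,,TRUE
mode_printed_material,printed material,presence_absence,,,TRUE
mode_group_delivery,group based delivery,presence_absence,,,TRUE
mode_individual_delivery,individual delivery,presence_absence,,,TRUE
source_physician,delivered by physician,presence_absence,,,TRUE
source_nurse,delivered by nurse,presence_absence,,,TRUE
source_psychologist,delivered by psychologist,presence_absence,,,TRUE
source_pharmacist,delivered by pharmacist,presence_absence,,,TRUE
setting_primary_care,primary care setting,presence_absence,,,FALSE
setting_hospital,hospital setting,presence_absence,,,FALSE
setting_workplace,workplace setting,presence_absence,,,FALSE
setting_community,community setting,presence_absence,,,FALSE
pop_pregnant_smokers,pregnant smokers population,presence_absence,,,FALSE
pop_adolescents,adolescent population,presence_absence,,,FALSE
pop_hospitalized_patients,hospitalised patient population,presence_absence,,,FALSE
pop_mean_age,mean age of participants,value,,years,FALSE
pop_pct_female,percentage of female participants,value,,percent,FALSE
pop_sample_size,number of participants randomised,value,,participants,FALSE
pop_cigarettes_per_day,mean cigarettes smoked per day,value,,cigarettes,FALSE
pop_years_smoking,mean years of smoking,value,,years,FALSE
pop_ftnd_score,mean nicotine dependence score,value,,points,FALSE
pop_pct_employed,percentage of employed participants,value,,percent,FALSE
pop_mean_quit_attempts,mean number of previous quit attempts,value,,attempts,FALSE
dose_number_of_sessions,number of intervention sessions,value,,sessions,TRUE
dose_session_duration_minutes,session duration,value,,minutes,TRUE
dose_intervention_duration_weeks,intervention duration,value,,weeks,TRUE
outcome_abstinence_1m,percentage achieving 1-month abstinence,value,,percent,TRUE
outcome_abstinence_3m,percentage achieving 3-month abstinence,value,,percent,TRUE
outcome_abstinence_6m,percentage achieving 6-month abstinence,value,,percent,TRUE
outcome_abstinence_12m,percentage achieving 12-month abstinence,value,,percent,TRUE
pop_ethnicity,ethnic group,presence_absence,,,FALSE
pop_pct_white,percentage of White participants,complex_component,pop_ethnicity,%,FALSE
pop_pct_black,percentage of Black participants,complex_component,pop_ethnicity,%,FALSE
pop_pct_asian,percentage of Asian participants,complex_component,pop_ethnicity,%,FALSE
pop_pct_other_ethnicity,percentage of other ethnicity participants,complex_component,pop_ethnicity,%,FALSE
pop_education,education level,presence_absence,,,FALSE
pop_pct_no_qualification,percentage with no formal qualification,complex_component,pop_education,%,FALSE
pop_pct_secondary_education,percentage with secondary education,complex_component,pop_education,%,FALSE
pop_pct_higher_education,percentage with higher education,complex_component,pop_education,%,FALSE
outcome_pct_followed_up,percentage followed up at final assessment,value,,percent,TRUE
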