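# Rule counts and task-kind coverage per bundled ruleset.
htn:
  n_rules: 8
  task_kinds: [RiskAssessment, HierarchicalManagement, RegularFollowUp,
               AbnormalConditionIntervention, MedicationGuidance,
               LifestyleGuidance, HealthEducation, ComplianceManagement]
t2dm:
  n_rules: 8
  task_kinds: [RiskAssessment, HierarchicalManagement, RegularFollowUp,
               AbnormalConditionIntervention, MedicationGuidance,
               LifestyleGuidance, HealthEducation, ComplianceManagement]
copd:
  n_rules: 7
  task_kinds: [RiskAssessment, HierarchicalManagement, RegularFollowUp,
               AbnormalConditionIntervention, LifestyleGuidance,
               HealthEducation, ComplianceManagement]
hm:
  n_rules: 2
  task_kinds: [LifestyleGuidance]
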