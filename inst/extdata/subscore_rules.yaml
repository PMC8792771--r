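# Default functional-system subscore rules.
#
# One block per functional system.  `finding_patterns` are case-insensitive
# keyword patterns for clinical findings relevant to the system;
# `severity_map` maps severity adjectives (in increasing order of severity)
# to an integer subscore; `default_score` is returned when a finding pattern
# matches a sentence that contains no severity adjective.  The first
# sentence of the note that matches any finding pattern decides the score.
#
# The full rule tables used in specialist MS clinics derive from the
# Neurostatus definitions of the neurological examination and are not
# public; this file is a documented, editable stand-in that covers all
# eight systems.  Correctness of the extractor is defined against this
# file, not against Neurostatus itself.
pyramidal:
  max_score: 6
  finding_patterns: [weakness, paraparesis, hemiparesis, spasticity, hyperreflexia]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5, profound: 6}
  default_score: 2
cerebellar:
  max_score: 5
  finding_patterns: [ataxia, dysmetria, intention tremor, dysdiadochokinesia]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5}
  default_score: 2
brainstem:
  max_score: 5
  finding_patterns: [nystagmus, dysarthria, dysphagia, diplopia, internuclear ophthalmoplegia]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5}
  default_score: 2
sensory:
  max_score: 6
  finding_patterns: [numbness, paresthesia, sensory loss, decreased vibration, proprioceptive loss]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5, profound: 6}
  default_score: 2
bowel_bladder:
  max_score: 6
  finding_patterns: [urinary urgency, urinary hesitancy, incontinence, urinary retention, indwelling catheter, constipation]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5, profound: 6}
  default_score: 3
visual:
  max_score: 6
  finding_patterns: [optic neuritis, scotoma, decreased visual acuity, visual field deficit, disc pallor]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5, profound: 6}
  default_score: 2
cerebral:
  max_score: 5
  finding_patterns: [cognitive impairment, memory deficit, fatigue, depression, mentation]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5}
  default_score: 2
ambulation:
  max_score: 6
  finding_patterns: [gait impairment, walking difficulty, uses a cane, uses a walker, wheelchair, bilateral support]
  severity_map: {minimal: 1, mild: 2, moderate: 3, significant: 4, severe: 5, profound: 6}
  default_score: 3
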