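# Cohort publication-type configuration for clinical-trial title selection.
# Canonical names follow the MEDLINE controlled vocabulary; the alias table
# maps common prose names onto canonical names (matching is case-insensitive).
version: "pubtypes-v1"
include:
  - Clinical Trial
  - Clinical Trial, Phase I
  - Clinical Trial, Phase II
  - Clinical Trial, Phase III
  - Clinical Trial, Phase IV
  - Randomized Controlled Trial
  - Pragmatic Clinical Trial
  - Controlled Clinical Trial
exclude:
  - Biography
  - Case Reports
  - Classical Article
  - Clinical Conference
  - Comment
  - Congresses
  - Consensus Development Conference
  - Duplicate Publication
  - Editorial
  - Guideline
  - Historical Article
  - Legal Cases
  - Letter
  - News
  - Patient Education Handout
  - Portraits
  - Retracted Publication
  - Review
aliases:
  randomized clinical trial: Randomized Controlled Trial
  randomised clinical trial: Randomized Controlled Trial
  randomised controlled trial: Randomized Controlled Trial
  clinical trial of any phase: Clinical Trial
  patient education: Patient Education Handout
  handout: Patient Education Handout
  case report: Case Reports
  legal case: Legal Cases
  portrait: Portraits
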