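# Default context-categorization rules for firearm-term matches.
# Cues are lowercase phrases tested by containment against the match's
# context window. match_order is the order categories are tried for a
# single match (first cue that fires wins; fallback is `other`);
# note_precedence resolves multi-match notes to a single category.
version: "default-rules-1"
match_order:
  - name_contains_term
  - template_shot
  - other
  - treatment_care
  - guidance_education
  - assessment
  - exposure
note_precedence:
  - exposure
  - assessment
  - guidance_education
  - treatment_care
  - template_shot
  - name_contains_term
  - other
cues:
  exposure:
    - "hears gunshots"
    - "heard gunshots"
    - "gunshot wound"
    - "suffered a gsw"
    - "robbed at gunpoint"
    - "held at gunpoint"
    - "gun in his mouth"
    - "gun in her mouth"
    - "history of gunshot"
    - "shot in a drive-by"
    - "witnessed a shooting"
  assessment:
    - "no access to firearms"
    - "access to firearms"
    - "do you have any guns"
    - "no guns"
    - "talking about guns"
    - "guns in the home. locked up"
    - "guns, knives or pills"
  guidance_education:
    - "remove guns"
    - "make sure any guns"
    - "gun safety"
    - "blasting caps"
  treatment_care:
    - "shooting pain"
    - "hepatitis"
    - "dmpa"
    - "cortisone"
    - "immunization"
    - "vaccine"
    - "flu shot"
    - "birth control shot"
  template_shot: []
  name_contains_term:
    - "provider name"
  other:
    - "nailgun"
    - "snap shot"
template_phrases:
  - "[shot for birth control: care instructions.]"
  - "[flu shot: care instructions.]"
injectable_cues:
  - "immuniz"
  - "vaccin"
  - "hepatitis"
  - "dmpa"
  - "cortisone"
  - "birth control"
  - "\\bflu\\b"
  - "depo"
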