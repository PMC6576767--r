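code,category
250.x,diabetes
296.2,depression
296.3,depression
311,depression
300.0x,anxiety
295.x,psychoses
650,pregnancy
V22.x,pregnancy
401.x,hypertension
493.x,chronic_pulmonary
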