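# Termination-table fixtures

Four subject x VOI binary tables transcribed from the published
20-subject IFOF dissection study these fixtures accompany: anterior
(frontal) and posterior (parietal/occipital/temporal) terminations for
the left and right hemispheres.

Format: one subject per row; `Y` marks successful bundle identification;
VOI entries are `0`, `1`, or `1*` where the asterisk carries the source
tables' footnote "very few streamlines reached the VOI" (loaded as
indicator 1 with a flag). `loadTableFixtures()` verifies each file
against a recorded md5 checksum and per-table flag count before use.

Known source inconsistency: the study's discussion text quotes 30% for
the left cuneus, while its results text and the table itself give 35%
(7 of 20 subjects). The fixture follows the table.
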