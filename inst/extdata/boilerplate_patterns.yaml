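# Default boilerplate / identifier patterns removed before any other
# preprocessing.  Each entry is a Perl-compatible regular expression matched
# case-insensitively against whole lines (anchors refer to line boundaries);
# a matching line is dropped.  Real EHR exports differ between institutions:
# edit or replace this file to match your dialect.  The defaults target the
# header/footer templates used by the synthetic note generator.
line_patterns:
  - '^\s*fax(\s*(number|no\.?))?\s*:.*$'
  - '^\s*(tel|telephone|phone)(\s*(number|no\.?))?\s*:.*$'
  - '^\s*document\s+(number|no\.?)\s*:.*$'
  - '^\s*(mrn|medical record number|patient id(entification)?( number)?)\s*:.*$'
  - '^\s*date\s+of\s+(visit|birth|service)\s*:.*$'
  - '^\s*(visit\s+)?date\s*:.*$'
  - '^\s*time(\s+of\s+visit)?\s*:.*$'
  - '^\s*(patient|physician|provider|re)\s*:.*$'
  - '^\s*address\s*:.*$'
  - '^\s*dictated\s+by\b.*$'
  - '^\s*electronically\s+signed\b.*$'
  - '^\s*sincerely,?\s*$'
  - '^\s*dr\.\s+[a-z]+\s+[a-z]+\s*,?\s*(md|frcpc)?\.?\s*$'
# Inline patterns are removed wherever they occur within a line.
inline_patterns:
  - '\b\d{3}[-.]\d{3}[-.]\d{4}\b'
  - '\b\d{1,2}[/-]\d{1,2}[/-]\d{2,4}\b'
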