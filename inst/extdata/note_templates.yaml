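# Template library for the synthetic clinic-note generator.
#
# Placeholders: {patient} {physician} {date} {phone} {doc} in headers and
# footers; {value} (digit form, e.g. 6.0), {prev} (a different digit value)
# and {words} (spelled-out form, e.g. "six") in score sentences;
# {adjective} in finding sentences.  Class phrases are keyed by the EDSS
# class written with one decimal; they paraphrase the clinical anchors of
# each half-step (ambulation distances, aid requirements, functional-system
# burden) and deliberately contain no digits, so only explicit score
# sentences ever place a number next to the keyword "EDSS".
headers:
  - |-
    Patient: {patient}
    MRN: {mrn}
    Date of visit: {date}
    Fax: {phone}
    Document number: {doc}
  - |-
    RE: {patient}
    Patient ID: {mrn}
    Visit date: {date}
    Tel: {phone}
footers:
  - |-
    Dictated by {physician}.
    Electronically signed {date}.
  - |-
    Sincerely,
    {physician}, MD
openers:
  - Thank you for asking me to review this pleasant patient with relapsing remitting multiple sclerosis.
  - I reviewed this patient with multiple sclerosis in follow up at the clinic today.
  - This patient with a longstanding history of multiple sclerosis returns for routine follow up.
  - It was a pleasure to see this patient with multiple sclerosis in the clinic again.
explicit_current:
  - "EDSS is {value} in this visit."
  - "Her EDSS score today is {value}."
  - "Current EDSS is {value}."
  - "I would rate the EDSS at {value} today."
distractor_pair:
  - "EDSS was {prev} in the previous visit. EDSS is {value} in this visit."
  - "she previously had an EDSS score of {prev} and her current score is of {value}"
spelled_out:
  - "EDSS was {words}."
  - "Her EDSS today is roughly {words}."
closers:
  - We will continue the current disease modifying therapy and review again in six months.
  - I have arranged repeat imaging and will see the patient back in clinic.
  - We discussed symptomatic management and the patient will follow up as planned.
band_fillers:
  - "Overall impression is of {band} disease burden at present."
  - "In summary the clinical picture suggests {band} accumulated deficit."
band_vocab:
  "b0": [quiescent, reassuring, negligible]
  "b1": [slight, minor, trivial]
  "b2": [definite, notable, evident]
  "b3": [substantial, considerable, pronounced]
  "b4": [marked, extensive, heavy]
  "b5": [advanced, devastating, overwhelming]
class_phrases:
  "0.0":
    - Neurological exam remains normal.
    - Detailed neurological examination is entirely normal today.
  "1.0":
    - Examination shows minimal signs only, with no disability whatsoever.
    - There are minimal findings and no disability whatsoever on review of systems.
  "1.5":
    - Minimal signs are present across several systems though disability is absent.
    - Scattered minimal signs in several systems, disability remains absent.
  "2.0":
    - There is mild disability confined to one functional domain.
    - Mild disability confined to a solitary domain on examination.
  "2.5":
    - Mild disability is apparent in two separate domains.
    - Examination demonstrates mild disability across two domains.
  "3.0":
    - Moderate disability is evident although the patient remains fully ambulatory.
    - Fully ambulatory, with moderate disability in one domain.
  "3.5":
    - Moderate disability with additional lesser findings combined across domains.
    - Several findings combined amount to moderate disability overall.
  "4.0":
    - Fully ambulatory without aid, managing five hundred meters without rest.
    - The patient walks five hundred meters unaided before needing rest.
  "4.5":
    - Ambulatory without aid for roughly three hundred meters despite some limitation of activities.
    - Walks three hundred meters without aid, with some limitation of full activities.
  "5.0":
    - Ambulatory without aid for about two hundred meters.
    - The patient manages two hundred meters unaided before stopping.
  "5.5":
    - Ambulatory without aid for one hundred meters at most, precluding full activities.
    - Walks barely one hundred meters unaided, which precludes full daily activities.
  "6.0":
    - Requires unilateral assistance, using a cane to cover one hundred meters.
    - Now walking with a cane, unilateral support for about one hundred meters.
  "6.5":
    - Requires constant bilateral assistance, two crutches, to walk twenty meters.
    - Bilateral support with crutches is needed to manage twenty meters.
  "7.0":
    - Essentially restricted to a wheelchair although transfers remain independent.
    - The patient is wheelchair bound but wheels self and transfers alone.
  "7.5":
    - Unable to take more than a few steps, requiring help with wheelchair transfers.
    - Only a few steps possible; transfers into the wheelchair require assistance.
  "8.0":
    - Essentially restricted to bed or chair, though self care is largely retained.
    - Confined to bed or chair for most of the day with retained self care.
  "8.5":
    - Restricted to bed much of the day, retaining some effective use of the arms.
    - Largely bedbound through the day with some effective arm function remaining.
  "9.0":
    - A helpless bed patient who can still communicate and eat.
    - Helpless and bedbound, although communication and eating are preserved.
  "9.5":
    - Totally helpless, unable to communicate effectively or to swallow.
    - Entirely helpless, without effective communication and unable to swallow.
finding_sentences:
  pyramidal: "There is {adjective} weakness of the lower extremities."
  cerebellar: "{adjective} ataxia is noted on cerebellar testing."
  brainstem: "{adjective} dysarthria is apparent in conversation."
  sensory: "She reports {adjective} numbness of the distal extremities."
  bowel_bladder: "{adjective} urinary urgency persists."
  visual: "{adjective} decreased visual acuity on the left."
  cerebral: "{adjective} cognitive impairment was evident on screening."
  ambulation: "{adjective} gait impairment was observed in the hallway."
finding_absent:
  pyramidal: "Power is full throughout."
  cerebellar: "Cerebellar testing is unremarkable."
  brainstem: "Cranial nerve examination is unremarkable."
  sensory: "Sensation is intact throughout."
  bowel_bladder: "Bowel and bladder function are preserved."
  visual: "Visual acuity is preserved bilaterally."
  cerebral: "Cognition is preserved."
  ambulation: "Gait is unremarkable."
catheter_sentence: "An indwelling catheter is in place."
patients:
  - Jane Morrison
  - Alan Whitfield
  - Priya Raman
  - Marco Silva
  - Lena Kowalski
  - Omar Haddad
  - Grace Chen
  - Samuel Osei
physicians:
  - Dr. Ellen Park
  - Dr. Robert Ames
  - Dr. Farah Noor
  - Dr. Victor Lindqvist
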