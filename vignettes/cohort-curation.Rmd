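---
title: "Curating large CT cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating large CT cohorts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortforge)
```

## The problem

Assembling an imaging dataset for machine learning sounds like a database
query: select the exams, pull the files. In practice the research registry
that identifies the cohort and the clinical PACS that stores the images are
different systems with different identifier conventions, different dates,
and different ideas of what an "exam" is. A cohort of tens of thousands of
abdominal CTs will contain mislabeled interventional procedures, medical
record numbers (MRNs) whose leading zeros were dropped on export,
accessions carrying a legacy prefix from a pre-migration EMR, accessions
generated purely for billing with no images behind them, images filed
under the pelvis or chest accession of a multi-part exam, exam dates that
disagree with PACS study dates by a few days, and a residue of studies
that are simply unusable: topogram-only, corrupted, missing, test
phantoms, or mis-encoded DICOM.

`cohortforge` implements that curation pipeline as composable, audited
stages, together with a synthetic RIS/PACS fixture generator that injects
each of these failure modes at configurable frequencies with per-exam
ground truth, so every rule in the pipeline can be scored exactly. The
packaged `paper_replica_config()` preset reproduces, at full scale, the
attrition profile of a published three-hospital retrieval of 23,186
abdominal CTs.

## Pipeline stages

**Registry filtering** (`apply_registry_filters`). A row is kept iff it
passes every filter: modality CT, exam year 2012, description containing
"Abd" (case-insensitive), exam group not in
{chest, hdnk, unclassified, resp, lextr, cspin}, patient type not
inpatient, and age in [18, 99]. Both age bounds are inclusive — we read
"between 18 and 99" inclusively, the convention for adult-cohort
definitions. Rows with an unparseable date or age are quarantined with a
reason rather than dropped, so stage counts always telescope.

**Earliest exam per patient** (`select_earliest_per_patient`). Ties on the
exam date are broken by exam time when recorded, then by lexicographic
accession. A record with a recorded time sorts before one without, on the
view that a known-earlier acquisition should win over an unknown one; any
fixed convention would do, what matters is that the choice is
deterministic and independent of input row order (property-tested over
permutations).

**Keyword exclusion** (`apply_keyword_exclusion`). Registry group labels
are unreliable; interventional and musculoskeletal CTs masquerade as
abdominal exams. A record is excluded iff its lowercased description
contains any of twelve keywords (ablation, fna, biopsy, drainage,
guidance, drain, drg, bx, interventional, interv, perc, bone) as a
substring. Substring semantics make "drainage" redundant given "drain";
it is retained because the operative list in the field includes both.

**Identifier normalization** (`normalize_cohort`). Rules are per-site
data, not code: an MRN pad width and an accession prefix to strip. Padding
is applied to non-numeric MRNs as-is (no digit constraint is imposed,
since none is documented); such MRNs are surfaced in an audit vector. The
prefix is stripped at most once from the left — the legacy export added it
exactly once, so `"AA123"` deliberately normalizes to `"A123"`. Raw values
are always carried alongside canonical ones so the reformatting count is
auditable.

**Accession resolution** (`resolve_cohort`). The image-bearing accession
is re-derived de novo by querying the PACS index with (canonical MRN, exam
date). Candidates are CT studies with strictly more than 20 images — the
floor that removes billing shells and partial imports of outside scans.
The cascade then prefers, in order: same-date studies with body part
abdomen/GI/GU/body; same-date pelvis, then same-date chest; and the same
body-part preference repeated over a ±4-day window. Three choices here
were genuinely open:

* *Within-tier tie-breaks.* The documented cascade is silent on ties. We
  use smallest absolute date difference, then largest image count, then
  lexicographic accession: date proximity and image count both favor the
  most plausible image-bearing study, and the accession tie-break makes
  the choice total and order-invariant.
* *Pelvis before chest.* The pelvis accession is the more common linkage
  target for an abdomen/pelvis exam; chest is permitted only "if
  necessary".
* *Date expansion re-runs the full body-part cascade* over the ±4-day set
  rather than only the abdomen tier, mirroring the "criteria above"
  phrasing of the source procedure. Note the tier structure already
  guarantees a same-date pelvis beats a 3-days-away abdomen study.

Body-part strings are folded through a configurable vocabulary
(`normalize_body_part`) mapping site spellings to
{abdomen, gi, gu, body, pelvis, chest, other}; `other` is never
selectable.

When fixture ground truth is available, `flag_misresolutions` scores
every resolution against the true image-bearing accession and emits an
override table; `apply_resolution_overrides` replays it, modeling the
manual corrections a curation team applies to the handful of exams the
deterministic cascade gets wrong.

**Triage** (`triage_cohort`). Each exam receives exactly one disposition,
applied in a fixed precedence order: MRN/ACC discrepancy (the PACS MRN
recorded for the exam's accession conflicts with the canonical registry
MRN), then missing (no resolvable study), then — for retrieved studies —
encoding error (undecodable metadata), corrupted (metadata parses, pixel
payload does not), topogram-only (every decodable instance is a
localizer, for studies of at most 5 instances), and non-patient test exam
(PatientName matching TEST/PHANTOM/ZZZ patterns). The precedence is a
design choice — the source counts are disjoint but unordered — and puts
identifier-level faults above content-level faults because an exam whose
identity is in doubt is unusable regardless of its pixels.

Content checks run for the studies listed in a retrieval manifest
(directories under `dicom_root`); a manifest-listed study whose directory
is absent is triaged as missing with distinct evidence. Studies outside
the manifest pass content checks vacuously — the metadata-only mode used
when pixel data is not staged locally. In the synthetic fixtures the
manifest covers every content-failure study plus a clean sample, so
category counts remain exactly scoreable.

**Attrition accounting** (`build_attrition_report`). The stage table
telescopes from registry rows to final valid exams; any violation of the
partition (a disposition missing, duplicated, or unknown) is a hard error
naming the offending exams, never a silent correction.

## The transfer capacity model

Bulk retrieval stages studies through an intermediate archive whose
buffer is drained to research storage. `simulate_transfer` is a
closed-form fluid model in study granularity: while the producer is
active the buffer grows at `push − write`; overflow occurs at
`capacity / (push − write)` active hours; otherwise the transfer
completes at `volume / min(push, write)`. A zero write rate with the
volume inside the buffer is reported as a *stalled* scenario rather than
an error. A `nightly_window` of `h` hours/day converts active time to
wall clock by the duty cycle `h/24`, modeling retrieval restricted to
nights. Study size variation is out of scope (no sizes are documented);
the model's contract is verified against an independent discrete-event
simulation to within one study granularity, and overflow is
property-tested to be monotone in capacity and push rate. Wall-clock
duration claims (weeks versus a year) are scenario outputs, not
calibrated quantities.

## The synthetic fixture generator

`generate_fixture` emits a registry export, per-hospital PACS indices, a
ground-truth label table and a DICOM retrieval manifest, deterministically
from a seed (byte-identical reruns are part of the test contract). Each
cohort exam carries exactly one injected mode; the generator's conservation
property — ground-truth mode counts equal the configuration exactly — is
what makes the pipeline scoreable.

Constructions worth noting:

* *Dropped zeros / legacy prefix* apply only at the first roster site,
  mirroring the single-hospital formatting problem; canonical forms for
  those exams draw MRNs below 10^7 so the 8-digit canonical form really
  has leading zeros to drop.
* *Billing-only* accessions appear in the index with zero images;
  *linkage* exams have a ≤20-image partial import under the registry
  accession and the true images under a same-date pelvis or chest study.
* *MRN/ACC discrepancy* exams file the registry accession under a foreign
  MRN while the patient's own MRN has no studies, so resolution fails and
  triage finds the conflicting pair — keeping the category disjoint from
  *missing*, which has no index row at all.
* *Adversarial* records plant a decoy same-date abdomen study (the
  registry accession) above the true pelvis-linked study, so the cascade
  provably picks the decoy; the construction is verified by running the
  resolver during generation and is one plausible mechanism for
  mis-resolution, chosen for testability, not a claim about any real
  archive.
* *Later exams* for a subset of patients are at least 5 days after the
  earliest, so the ±4-day window can never capture a sibling study.
* *Decoy rows* (500 in the replica) each violate exactly one upstream
  filter; the full upstream registry is deliberately not generated at its
  original multi-million-row bulk, which would add nothing but volume to
  what the filters are tested on.

DICOM rendering (`render_dicom_fixtures`) writes genuine Part 10 files in
Explicit VR Little Endian — preamble, file meta group, and a dataset with
patient/study attributes and a small 8×8 synthetic gradient image —
through the package's own minimal writer (`dicom_write_instance`), with
defect switches for each content failure: all-localizer image types,
truncated pixel payloads under a full declared length, an invalid value
representation that makes the dataset undecodable, and sentinel patient
names. Files are cross-checked in the test suite against an independent
DICOM reader. Only manifest studies are rendered (the replica renders 36:
26 content failures plus 10 clean), keeping the fixture at desk scale;
pixel content is synthetic gradients by design — nothing in triage
depends on clinically realistic pixels.

### The replica preset

Several of the preset's internal splits are not documented by the source
counts and were fixed once, at values a curation team would find
plausible; every printed count is invariant to them:

* the 838 resolved-to-a-different-accession exams split 280 billing-only,
  300 pelvis-linked, 258 chest-linked;
* the 10,089 reformatted exams split 6,000 dropped-zero MRNs and 4,089
  prefixed accessions;
* 500 exams carry a PACS date offset of ±1–4 days (the documented reason
  the window expansion exists; offset exams resolve to their own
  accession, so the count does not interact with any printed figure);
* 9,996 patients contribute one later exam each (33,182 rows for 23,186
  patients);
* injected modes are assigned to disjoint exams. Real data surely
  overlaps (a prefixed accession can also be pelvis-linked); the disjoint
  construction is what makes each documented count recoverable exactly,
  and nothing in the pipeline depends on it.

### What passing the replica does and does not show

The fixture demonstrates that the pipeline's rules recover every injected
failure with 100% sensitivity and specificity *under the generator's
assumptions*: disjoint failure modes, canonical PACS identifiers, a
single-site formatting problem, accession-unique studies, and failure
frequencies taken from one institution's experience. Real registries
violate several of these (overlapping faults, multi-site quirks,
free-text body parts beyond the vocabulary), so green tests here are
evidence of rule correctness, not of expected yield on new data.

## Problem sizes and runtime

The test suite runs the full replica once (33,682 registry rows, ~35,000
index rows, 36 rendered studies; about 3 s) and otherwise uses 150-patient
fixtures exercising every injection mode, 400+ randomized resolver
candidate sets against a brute-force cascade oracle, and 60-scenario
transfer sweeps against the discrete-event oracle. These sizes were chosen
so the whole suite completes in well under a minute while still covering
every branch of every rule.

## Known limitations

* The DICOM layer reads and writes only what triage needs (Explicit VR
  Little Endian, single-frame monochrome); it is not a general codec.
* Accessions are assumed unique within an index; collision across
  hospitals is not modeled.
* The transfer model is study-granular and deterministic; bursty arrivals
  and size heterogeneity are out of scope.
* Date offsets are bounded at ±4 days because that is the resolver's
  documented expansion; larger registry/PACS disagreements would surface
  as missing exams.
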