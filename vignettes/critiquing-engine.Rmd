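---
title: "From structured recommendations to prescription critiques: models, algorithms and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From structured recommendations to prescription critiques}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxcritic)
```

rxcritic critiques physician drug prescriptions against a declarative model
of a clinical practice guideline's therapeutic recommendations. This
vignette is the package's methodological account: the knowledge model and
its assumptions, the compilation algorithms, the matching and inference
semantics, the verification machinery, and the design decisions taken where
the problem was genuinely open.

## The knowledge model

### Drug classes and ATC membership

Drugs are identified by their ATC (Anatomical Therapeutic Chemical) code, a
hierarchical alphanumeric code of up to seven characters. A drug class is a
*set of code prefixes*: a drug belongs to the class iff any prefix matches
the start of its full code. This supports classes at any level of the
hierarchy — `A10B` (all oral antidiabetics), `A10BA` (biguanides) — and
classes that no single code covers (the glinides need both `A10BX02` and
`A10BX03`). Class names are KB-local identifiers; codes are upper-case
ASCII.

A practical caveat surfaced while building the diabetes example: generic
rules that are generated *per pharmaco-therapeutic class* (non-represcription
after intolerance, no same-class association) must not range over broad
umbrella query classes like `A10B`, or intolerance to one biguanide would
block every oral antidiabetic. The generic-recommendation configuration
therefore supports `partial` applicability with an explicit class scope, and
the bundled KBs scope those rules to the specific classes.

### Treatment patterns

A treatment pattern is a query, never a concrete treatment. Its component
patterns constrain class membership, dose, pharmaceutical form and per-drug
tolerance; treatment-level constraints cover status (past / current /
proposed), efficacy, failure ("ineffective or contains a poorly tolerated
drug"), relative-posology changes, drug-component cardinality (so
"monotherapy" counts drugs only — diet does not count), and a recency
window. Matching requires an **injective** assignment of component patterns
to *distinct* treatment components: one drug cannot satisfy two slots, which
is what lets a two-slot same-class pattern mean "two distinct drugs of class
C". A pattern without a wildcard must cover the treatment exactly; the `Any`
wildcard absorbs leftover components within its repeat bounds. Patterns
without a status constraint match treatments of every status, including the
proposal — stage conditions and compiled rules therefore always set the
status explicitly.

Dose comparison requires identical units and dosing periods; there is no
unit conversion. A silent mg/g bug is worse than asking KB authors to
normalize units, so a mismatch is simply a non-match.

### Recommendations and criticism labels

Three recommendation types cover the therapeutic recommendations we model:

* `should_prescribe`: N ordered lines of recommended treatments, line N+1
  implicitly standing for "any other treatment" (a patient is never *at*
  stage N+1, but can certainly be *prescribed* a line-N+1 treatment);
* `should_not_prescribe`: a forbidden pattern under conditions;
* `increasing_power`: N levels ordered by increasing therapeutic power.

`should_prescribe` recommendations carry an explanation label per line
2..N+1 (why this line is not yet indicated), an advice label per line 1..N
(what is recommended at the patient's stage) and one reference label. A
criticism is the concatenation *explanation(Y) + advice(X) + reference*, so
rules sharing a stage share their advice fragment and rules sharing a
proposed line share their explanation fragment. Label coverage is checked
statically at load time: every (X, Y) pair a rule can reach must have
non-empty labels, so every criticism the engine can ever emit is composable
from the KB.

Recommendations with several lines are deliberately *not* split into
one-line recommendations: "second-line" is only meaningful relative to the
first line, so the lines must stay within one recommendation.

## Compilation

### Stage conditions

The patient is at the stage of line X iff ("failed" = ineffective or poorly
tolerated, over past and current treatments):

* X = 1 — no failed treatment of any line in the history;
* 2 ≤ X ≤ N−1 — no failed treatment of line ≥ X, and a failed treatment of
  line X−1;
* X = N — a failed treatment of line N−1 or N.

These clauses partition the histories: exactly one stage holds, whatever
failures the history contains (failures of non-line treatments are
invisible to all clauses and never advance the stage — the clauses quantify
over the recommendation's own lines only). For N = 1 the clauses degenerate
and would leave a patient with a failed line-1 treatment stage-less; since a
one-line recommendation has a single stage, we take its stage condition as
vacuously true, preserving totality and uniqueness.

### Rule generation

`should_prescribe` yields one rule per pair (X, Y), 1 ≤ X ≤ N,
X+1 ≤ Y ≤ N+1 — N(N+1)/2 rules:

> if (conditions) and (patient at stage X) and (proposal is a line-Y
> treatment) and (proposal is not a treatment of any line < Y) then
> criticism(X, Y).

The "not a line < Y" clause matters because lines may overlap (e.g.
simvastatin as first-line, *any statin* as second-line): only the lowest
matching line counts. No rules are generated for Y ≤ X — re-prescribing at
or below the stage is policed by the generic rules, not here. Line-N+1
membership is compiled as "matches no declared line".

`should_not_prescribe` yields one rule. `increasing_power` with N levels
yields N−1 rules, one per proposed level X in 1..N−1: the rule fires when a
*more powerful* level Y > X was already ineffective — prescribing a weaker
treatment than one that failed is pointless. (Indexing the rules by the
proposed level X from 1 to N−1 is the only reading under which the count
N−1 and the semantics agree: the top level has no stronger level to have
failed, and the weakest level is exactly the one that must be criticized
most.)

### Generic recommendations

Eight guideline-independent recommendations supply the implicit knowledge:
three single rules for dose handling (#2 ineffective-but-tolerated ⇒ don't
reduce; #3 too effective ⇒ don't increase; #4 poorly tolerated ⇒ don't
increase), one rule for treatment continuity (#1), one rule per
recommendable treatment for recent inefficacy (#5, three-year window
measured from the treatment's end date to the critique date), one rule per
class for past intolerance (#6, the class must have been stopped — followed
by a treatment without it), and one rule per class against same-class
association (#8, two distinct drugs of the class in the proposal). #7 —
"if both poorly tolerated and ineffective, apply the poor-tolerance
recommendations" — produces no rule: `normalize_outcomes()` rewrites the
treatment's efficacy to `unknown` (tolerances are never altered) so only
the intolerance pathway can fire. The window applies to #5 and not #6
because inefficacy is circumstantial (a treatment ineffective years ago may
work after the patient changes) while intolerance is not.

Applicability is configured per KB: `not_applicable` drops the rules,
`partial` restricts them to a declared scope, and exceptions carve out
entities — e.g. bupropion is excluded from the dose-lowering advice because
of its narrow therapeutic range, so #4's rule does not reach
bupropion-containing proposals.

#5 matches treatments at recommendable-treatment granularity (same
components, same doses, no extras) rather than "any treatment containing
the same drugs": the rule is generated *per recommendable treatment*, and a
different dose of the same drug is a different therapeutic decision.

## Matching and inference semantics

Clinical predicates are (attribute, operator, value) triplets over the
record's clinical and biological values. Missing values are **fail-closed**:
the predicate is false and a missing-data note is accumulated and surfaced
in the result — a library cannot assume the dialog-box guarantees an
integrated record system provides. Similarly `unknown` tolerance or
efficacy never satisfies a constraint that requires a specific value.

The engine performs four steps: fire all rules on the proposal; concatenate
the criticisms of fired rules in deterministic compiler order (exact
duplicates once); compute suggestions by substituting each recommendable
treatment as the proposal (recomputing the relative-posology change flags
against the current treatment) and retaining those firing no rule; and if
no suggestion survives, relax — at level k the should-prescribe rules with
Y − X ≤ k are suppressed, so a second-line treatment becomes acceptable for
a first-line-stage patient, then a third-line one, and so on up to
k = max(N) − 1. "Any other treatment" rules (Y = N+1) are never suppressed:
relaxation can promote a *recommended* treatment across lines, never admit
a non-recommended one. If nothing survives maximal relaxation the result is
flagged `insufficient_guidance` — the guideline has nothing left to offer
(e.g. every recommended drug is not tolerated).

Relaxation applies to the *suggestion* computation only; the verdict on the
physician's proposal is always the strict one. Relaxing exists to find a
way forward, not to excuse the deviation, and reporting a relaxed verdict
would hide deviations precisely when the situation is hardest.

The data-enriching pass also derives the body mass index from height (m)
and weight (kg), and groups the proposed drugs by indication through the
KB's (class, dose range) indication map — aspirin's indication depends on
its dose; a beta-blocker indicated for both hypertension and atrial
fibrillation is duplicated into both groups and the critique runs once per
group. Outcomes are attributed per original treatment after duplication; KB
authors should be aware that a treatment spanning an indication boundary
carries its single efficacy value into every group.

Dates are calendar dates; history ordering is by start date with ties kept
in record order (stable). The verification tooling anchors its window
arithmetic at a fixed critique date (2026-01-01) so that scenario files
with absolute dates label deterministically.

## Verification

Two quality-assurance procedures treat the engine as a black box.

**Input-vector enumeration + tree regeneration.** The KB declares finite
value grids for a small set of attributes and named therapeutic-history
scenarios; the full cartesian product is enumerated and each vector is
labelled with the treatments the engine accepts for that profile (at the
smallest relaxation level with a non-empty set; "no treatment" when none
survives). Suggestion sets are encoded as one categorical label — a sorted,
comma-joined name tuple — because the induction step needs a single target;
treatments recommended only as second line or later are bracketed, as a
static property of the treatment's minimal line. An unpruned decision tree
is then induced with gain-ratio splitting over the categorical attributes
(multiway splits, recursion to label purity, ties broken by attribute
declaration order). Pruning is disabled so the training error is 0% by
construction and every enumerated vector routes to the exact engine label;
the tree is a human-reviewable regeneration of the KB that an expert can
compare against the source guideline. The induction is written here rather
than borrowed: the installed tree learners implement different algorithms
(cost-complexity CART, deviance splitting) and prune by default, and the
procedure's value lies in exact, unpruned regeneration. The vector space
must stay small for the tree to stay readable — the tooling is not meant
for KBs with combinatorial attribute spaces, and the bundled statin example
uses 8 vectors (2 × 2 grids × 2 history scenarios).

**Seeded test bases.** For each patient profile, one positive case per
treatment the engine recommends strictly (expected to conform) and five
random negative prescriptions drawn uniformly over (drug class, grid dose)
pairs, kept only if the engine actually criticizes them, so every emitted
negative fires at least one rule. If a profile lies outside every
recommendation's conditions fewer than five negatives may exist; they are
emitted with a warning. The same seed reproduces the same base exactly.

## Synthetic generators and what passing tests show

`synth_kb()` generates minimal valid knowledge bases — up to four disjoint
drug classes, one should-prescribe ladder of up to three single-class
lines, one recommendable treatment per line — and `synth_patient()` random
histories (each class contributes a past treatment with probability 0.5,
efficacy and tolerance drawn with realistic weights, sequential
non-overlapping date ranges) and a uniformly drawn single-drug proposal.
These sizes mirror the structure of real therapeutic recommendations
(2–3 lines is typical) while keeping exhaustive checking cheap. The
property suite runs the engine against an independent interpreter of the
ladder semantics on 120 such cases and checks stage uniqueness, suggestion
self-consistency and relaxation minimality.

What this does *not* show: the generators produce disjoint classes,
unconditioned recommendations and single-drug treatments, so they exercise
neither overlapping lines, nor clinical conditions, nor combination
therapies — those paths are covered by the hand-built example KBs, and
real guideline KBs will exercise them harder. The bundled KBs are toy
reconstructions of guideline fragments, not the full guidelines; counts and
behaviours measured on them say nothing about full-scale KB sizes.

## Numerical and degenerate-input choices

* The recency window is 3 years, computed as 365.25-day years from
  `end_date` to `critique_date`; current and proposed treatments are always
  inside the window.
* `compile_kb()` is pure: identical KBs give byte-identical JSON rule
  dumps, which the audit trail and the determinism tests rely on.
* Empty prescriptions yield an empty indication map; unmapped drugs are
  excluded from the critique with a warning rather than silently dropped.
* A KB with zero recommendations or zero recommendable treatments is
  rejected at load time, with *every* violation listed, not just the first.
* Contradictory duplicate records in tree induction (identical vector,
  different labels) are impossible with a deterministic engine but guarded
  with an explicit error.

## Known limitations

* Treatment durations are not modelled (only status and date ranges); a
  duration attribute would be a straightforward extension.
* No drug-interaction checking: that is the province of dedicated reminder
  systems, not guideline critiquing.
* Dose constraints record value, unit and period without interpreting
  whether a quantity is per intake or per day beyond exact matching —
  interpretation is left to KB authors, who must keep units consistent.
* Criticism text generation is label concatenation; there is no natural
  language generation and no ranking among suggestions beyond KB
  declaration order.
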