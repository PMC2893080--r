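# rxcritic

Rule-based critiquing of drug prescriptions against computerized clinical
practice guidelines.

## The problem

Clinical practice guidelines (CPGs) express therapeutic knowledge as ordered
preferences — *"prescribe metformin as first-line treatment, an
alpha-glucosidase inhibitor (AGI) as second-line"* — under clinical and
biological conditions. A **critiquing decision support system** inverts this
knowledge: it stays silent while the physician prescribes, and raises an
alert only when the prescription deviates from the guideline, explaining
*why*. Writing the underlying `if conditions then criticism` rules by hand
is error-prone: a single two-line recommendation already induces six
distinct (patient stage × proposed treatment) situations with three
different criticisms. rxcritic is for medical-informatics engineers and
knowledge-base authors who want to declare the recommendation once and have
the rules, the criticism texts, the treatment suggestions and the
verification artefacts generated mechanically.

## The model

A knowledge base (YAML) declares:

* **drug classes** as sets of ATC code prefixes (the ATC classification is
  hierarchical, so membership is prefix matching; a class such as the
  glinides needs several codes);
* **treatment patterns** — granularity-flexible queries over treatments
  ("diet + metformin 500 mg", "any bitherapy", "any treatment including a
  poorly tolerated statin") with status (past / current / proposed),
  efficacy, tolerance, relative-posology-change, cardinality and
  time-window constraints, and an `Any` wildcard absorbing zero or more
  extra components;
* **recommendations** of three types, with per-line criticism labels.

The compiler turns each recommendation into executable rules:

| type | rules generated |
|---|---|
| *one should not prescribe* | 1 |
| *treatments of increasing power*, N levels | N − 1 |
| *one should prescribe*, N lines | N(N + 1)/2 |

For a *should-prescribe* recommendation the rules range over pairs
(X, Y), 1 ≤ X ≤ N, X + 1 ≤ Y ≤ N + 1, where X is the **patient stage**
(inferred from which prior line treatments failed — were ineffective or
poorly tolerated) and Y the line of the proposed treatment (line N + 1 =
"any other treatment"). Each rule's criticism is the concatenation
*explanation label(Y) + advice label(X) + reference label*. Eight
guideline-independent **generic recommendations** add the implicit medical
knowledge CPGs omit (continue an effective well-tolerated treatment, adjust
doses on inefficacy / excess effect / intolerance, never re-prescribe what
recently failed, never combine two drugs of one class); the dual-failure
rule (#7) generates no rule but normalizes outcomes so the poor-tolerance
pathway wins.

The inference engine (1) fires the rules on the proposal, (2) composes the
textual critique, (3) computes suggestions by substituting every
recommendable treatment as the proposal and keeping those firing no rule,
and (4) **relaxes** the line rules step by step (accepting a line X + k
treatment for a stage X patient) until a suggestion survives — or reports
that the guideline provides insufficient guidance.

## Worked example

```r
library(rxcritic)
kb <- example_kb("diabetes")          # metformin 1st line, AGI 2nd line
compile_kb(kb, generics = FALSE)
#> <rx_ruleset> compiled from 'diabetes-type2-monotherapy': 3 rules (k_max = 1)

critique_matrix(kb)[, c("stage", "proposal", "conforms")]
#>   stage  proposal conforms
#> 1 stage1 metformin    TRUE
#> 2 stage1 agi         FALSE
#> 3 stage1 other       FALSE
#> 4 stage2 metformin    TRUE
#> 5 stage2 agi          TRUE
#> 6 stage2 other       FALSE
```

Three of the six situations are criticized, each with its own text; for a
stage-1 patient proposed an AGI the engine prints:

```
criticism: AGI should be prescribed only as second-line treatment.
           Guideline recommends metformin as first-line treatment.
suggestions: diet_metformin
```

Verification regenerates a knowledge base as an unpruned gain-ratio
decision tree over the full enumeration of its input vectors:

```r
kb <- example_kb("statins")
tree <- induce_tree(build_dataset(kb))   # 8 vectors, training error 0%
cat(render_tree(tree))
#> history = none:
#>   age = 60: diet_simvastatin, diet_pravastatin, diet_atorvastatin
#>   age = 85:
#>     prevention = primary: no treatment
#>     prevention = secondary: diet_simvastatin, diet_pravastatin, diet_atorvastatin
#> history = statins_failed:
#>   age = 60: [diet_rosuvastatin]
#>   ...
```

Bracketed treatments are recommended as second-line only. Results carry
broom-style `tidy()` / `glance()` methods and the tree an `autoplot()`.

A thin CLI wraps the same functions:

```sh
exec/rxcritic kb validate inst/extdata/diabetes.yaml
exec/rxcritic critique <kb.yaml> <patient.yaml>    # exit 0/1/2
exec/rxcritic verify inst/extdata/statins.yaml
```

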