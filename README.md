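# phedkit

Decision support for public-health emergencies, in two stages that usually
live in separate tools:

1. **Knowledge acquisition** — covering rough-set attribute reduction of
   event decision tables via the *family method*, with a cost-aware greedy
   algorithm (A-DRE) that treats reduction as a minimum-cost hitting set on
   the hypergraph of related families, plus decision-rule extraction
   (support / coverage) and ordered-rule classification.
2. **Scheme selection** — ranking candidate emergency response schemes whose
   evaluations are uncertain (scalars, intervals, linguistic terms) with an
   interval *cumulative prospect theory* model, and aggregating prospect
   matrices across departments through a consensus-weighted group matrix.

It is aimed at analysts building emergency decision pipelines: rough-set /
granular-computing researchers who need a tested reference implementation of
family-method reduction, and MCDM practitioners who need a grey
prospect-theory ranking that handles intervals and linguistic scales
end to end.

## The models in brief

A covering decision table is `(U, Δ, D)`: a universe of events, one covering
per condition attribute (blocks may overlap), and a decision partition. A
block is *effective* when it lies inside one decision class; `r(x)` is the
set of coverings owning an effective block containing `x`; a **reduct** is a
minimal set of coverings hitting every distinct `r(x)`. `all_reducts()`
enumerates all reducts through the discernibility function (CNF → minimal
DNF with absorption); `adre_reduce()` finds a cheap one greedily, maximising
uncovered-edges-per-cost, then prunes to minimality.

Scheme ranking values each grey entry relative to a per-criterion reference
point `R_j`, passes deviations through the prospect value function
`v(d) = d^α` (gains) / `−λ(−d)^β` (losses), weights state probabilities with
`π(p) = p^γ / [p^γ + (1−p)^γ]^{1/γ}` (γ = χ for gains, δ for losses), and
ranks schemes by `U_i = Σ_j ω_j · mid(V_ij)`. Defaults are the canonical
α = β = 0.88, λ = 2.25, χ = 0.61, δ = 0.69.

## Worked example

The package ships the six-object walkthrough table (five attributes, two
decision classes) used to validate every reduction step:

```r
library(phedkit)

tab <- worked_example_table()
related_family(tab)
#> <related_family> 6 objects, 4 distinct sets
#>   { C1, C3, C5 }
#>   { C1, C5 }
#>   { C2, C5 }
#>   { C1, C2, C3, C5 }

all_reducts(tab)
#> <reduct_formula> 4 clauses, 2 reducts
#>   { C5 }
#>   { C1, C2 }

adre_reduce(tab)                      # unit costs
#> <reduct> {C5}, total cost 1, minimal, positive region preserved
adre_reduce(tab, costs = c(C5 = 10))  # C5 now expensive
#> <reduct> {C1, C2}, total cost 2, minimal, positive region preserved

extract_rules(tab, adre_reduce(tab))
#> # A tibble: 5 × 7
#>    rank covering_id block_index block     decision_label support coverage
#> 1     1 C5                    3 <chr [3]> D1               0.5      1
#> 2     2 C5                    1 <chr [2]> D1               0.333    0.667
#> ...
```

The top rule reads: *if the event falls in block {x1, x2, x3} of attribute
C5, decide D1* — it matches half the universe (support 0.5) and the whole
D1 class (coverage 1), so it ranks first and wins any classification
conflict.

The three-scheme COVID-19 community rescue case (three criteria — case
health status, number of rescuers, equipment/labour cost — over four time
frames) runs through the prospect pipeline as:

```r
case <- covid_case_matrix()
cumulative_prospect(case$values, case$criteria, case$reference)
#> <prospect_result>
#>   x2  U = -1.8033  <- selected
#>   x3  U = -2.0253
#>   x1  U = -5.8401
```

Scheme x2 (medical team + ambulance + expert + equipment) is selected: all
utilities are negative — every scheme is perceived as a net loss against
the decision-maker's reference expectations — but x2 loses least, balancing
response capacity against cost. Absolute `U` values depend on the
configured linguistic scale and prospect parameters (see the methods
vignette); the ranking is the robust output.

Multi-department use stacks per-department prospect matrices and calls
`group_aggregate(matrices, criteria)`; see `vignettes/` for the model.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/phedkit reduce table.json
Rscript inst/cli/phedkit decide eval.json --config params.yaml
Rscript inst/cli/phedkit simulate table --objects 81 --coverings 15 --seed 1 --out t.json
```

Subcommands: `reduce`, `rules`, `classify`, `decide`, `group`, `simulate`;
output is stable JSON (exit 2 on usage errors, 1 on data errors).

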