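# dnacodes

Tools for designing robust codeword sets for DNA-based data storage.

Storing digital data in synthesized DNA requires codewords that survive
synthesis, PCR and sequencing. In practice that means joint
combinatorial constraints on a set of length-`n` words over
`{A, C, G, T}`: balanced GC content (`W` G/C bases per word), no
homopolymer runs ("no-runlength", NL), pairwise Hamming distance at
least `d`, Hamming distance at least `d` from every word's
*reverse complement* (RC, suppressing cross-hybridization), and no
self-complementary stems that fold into secondary structure. A set
satisfying the chosen constraints is a coding set
`C^{GC,NL,RC}(n, W, d)`; its size `K` certifies a lower bound on the
maximum achievable code size, and its coding rate

```
R = log4(K) / n
```

measures information density (nucleotides of payload per nucleotide
synthesized).

Finding large sets is NP-hard in general. This package constructs them
with a moth-flame metaheuristic (MFOS): a spiral-search population
optimizer augmented with Levy-flight and opposition-based-learning
mutation strategies and elitist arithmetic crossover, driving a greedy
set-growth loop that only ever accepts words with violation score
exactly zero — so every emitted set passes the package's independent
validator. Around this core the package provides the constraint
predicates, whole-set validation with itemized violation reports,
lower-bound tables with percentage comparisons against packaged
reference values, a 19-function benchmark harness with Wilcoxon
rank-sum comparison, nearest-neighbor melting-temperature analysis
(SantaLucia 1998 unified parameters), and a lossless binary-to-DNA
codec. It is aimed at researchers in DNA data storage and DNA computing
who need validated code sets, and at metaheuristics practitioners who
want a reproducible harness around the optimizer.

## Worked example

Construct a GC+NL-constrained set at `n = 5`, `d = 3`, validate it, and
compute its rate:

```r
library(dnacodes)

cfg <- code_search_config(dna_constraints(n = 5, d = 3), seed = 42)
cs <- construct_code_set(cfg)
cs
#> DNA code set: 23 words of length 5 [mfos search]
#>   ACGAC AGCTA AGTCG ATCAG ATGCT CAGAG CATGC CGATC ...

validate_codeset(cs)
#> Code-set validation: 23 words, PASS

coding_rate(length(cs), 5, digits = 3)
#> [1] 0.452
```

23 words meets and exceeds the published consensus size of 20 for this
cell; the rate 0.452 says each of the 5 nucleotides carries ~0.45
nucleotides of information. Rates and percentage comparisons truncate
toward zero (`digits =`), the convention used by published rate tables.

The optimizer is usable on its own, `optim()`-style:

```r
fit <- mfos(function(x) sum(x^2), lower = -100, upper = 100, v = 10,
            control = mfos_control(seed = 1))
fit
#> MFOS run: 500 iterations, 26709 evaluations
#>   best value: 9.45385e-18
```

Melting-temperature analysis and the rank-sum comparison:

```r
melting_temperature("ACGTATCAGA")   # 200 nM primer, 50 mM Na+
#> [1] 25.35
rank_sum_test(c(1, 2), c(3, 4))$p.value
#> [1] 0.3333333
```

A command-line entry point wraps the same functions:

```sh
Rscript inst/cli/dnacodes.R search --n 7 --d 5 --constraints gc,nl,rc \
    --seed 1 --out codes.cod
Rscript inst/cli/dnacodes.R rate --k 190 --n 12     # prints 0.315
Rscript inst/cli/dnacodes.R validate codes.cod
```

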