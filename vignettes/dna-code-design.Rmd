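---
title: "Designing constraint-satisfying DNA code sets with a moth-flame optimizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing constraint-satisfying DNA code sets with a moth-flame optimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacodes)
```

## The problem

DNA data storage writes digital payloads into synthesized
oligonucleotides. The address and payload words used for this must avoid
the sequence features that make synthesis, PCR and sequencing
error-prone: skewed GC content, homopolymer runs, near-identical word
pairs (which confuse readout), words close to other words' reverse
complements (which cross-hybridize), and self-complementary regions that
fold into hairpin-like secondary structure. A *coding set*
$C(n, W, d)$ collects length-$n$ words over $\{A, C, G, T\}$ with GC
count $W$ and pairwise Hamming distance at least $d$; superscripts name
the constraints enforced, e.g. $C^{GC,NL,RC}(n, W, d)$ adds the
no-runlength (NL) and reverse-complement (RC) rules. Every valid
constructed set certifies a **lower bound** on the largest possible code
size, and the **coding rate** $R = \log_4(K)/n$ of a $K$-word set
measures the information density achieved. The goal is simple to state
and combinatorially hard: find as many mutually compatible words as
possible.

## The constraint layer

`dna_constraints()` bundles $(n, W, d)$ with the constraint flags.
Decisions that were genuinely open and how we fixed them:

* **No-runlength** is read in its strictest form: no two adjacent equal
  symbols (`max_run = 1`). The rule exists to exclude homopolymers, and
  the strict reading is the only one under which "no runlength" is
  literally true; a configurable `max_run` is provided for milder
  regimes.
* **GC tolerance at odd $n$**: a length-7 word cannot have 50% GC, so
  both $\lfloor n/2\rfloor$ and $\lceil n/2\rceil$ are admitted by
  default (an exact-$W$ mode is available via `gc_tolerance`). Published
  length-7 sets contain both counts, which supports this reading.
* **RC pairs** are checked over *all ordered pairs including self-pairs*
  (a word against its own reverse complement), the standard convention
  in the combinatorial DNA-code literature; `rc_include_self = FALSE`
  relaxes it.
* **Secondary structure** is screened as stem existence: two disjoint
  subwords of length $m \ge$ `ss_min_stem` (disjointness
  $|i - j| > m$ on 1-based starts) that are mutually
  reverse-complementary. This is a screen, not a minimum-free-energy
  fold; it deliberately ignores loop energetics and G-U style wobble
  pairing, which do not exist for DNA-DNA duplexes anyway.

`validate_codeset()` applies all of this to a whole set and returns an
itemized report; a set is shipped by the search only if this report is
clean.

## The optimizer

`mfos()` is a population metaheuristic for box-constrained minimization.
Moths (matrix $Q$, fitness $Q_f$) spiral around flames (matrix $R$,
fitness $R_f$), the best positions found so far:

$$ q_i \leftarrow D_i\, e^{b t} \cos(2 \pi t) + r_j, \qquad
   D_i = |r_j - q_i|, $$

with $t \sim U[r, 1]$, $r$ annealed from $-1$ to $-2$ over the run,
$b = 1$, and the flame count annealed as
$\mathrm{round}(N - \mathrm{it}\,(N-1)/T)$ so late iterations exploit
around a single incumbent. Flames are rebuilt each iteration from the
merged moth + flame population, which makes the best-so-far trace
non-increasing by construction (elitism). Three auxiliary operators give
the "synergistic" variant (MFOS):

* **Levy-flight mutation** (probability `mutation_prob`, default 0.05):
  a Mantegna-generated heavy-tailed step with stability index
  $\beta = 1.5$, scaled by $0.01\,(ub - lb)$. Mostly tiny steps,
  occasionally long jumps out of local basins.
* **Opposition-based-learning (OBL) mutation** (same probability): the
  box reflection $lb + ub - x$, accepted greedily only when it improves.
* **Arithmetic crossover of the two best individuals** (probability
  0.8): a random convex combination of the top two flames, replacing the
  worst moth when better.

`mfos_control(variant = "mfo")` switches all three off, giving the plain
moth-flame baseline used in comparisons. Runs are fully deterministic
under `seed`. One iteration costs $O(N^2)$ for the sort-based flame
merge plus $O(Nv)$ for position updates, i.e. $O(T N^2 + T N v)$
overall; the returned `n_evals` makes the evaluation budget auditable.

```{r optimizer}
fit <- mfos(function(x) sum(x^2), lower = -100, upper = 100, v = 10,
            control = mfos_control(seed = 1))
fit
```

On this 10-dimensional sphere the default configuration reliably reaches
values far below $10^{-6}$; the paired comparison against the plain
baseline on multimodal problems is part of the test suite and the
acceptance script rather than a claim restated here.

## From continuous positions to codewords

The optimizer works on $[0, 4)^n$; `decode_vector()` floors each
coordinate to a digit and maps digits to bases as A=0, T=1, C=2, G=3 —
the same bijection the storage codec uses. This decoding is surjective
onto all $4^n$ words and is the minimal bridge between the continuous
search space and the discrete application; nothing in the method depends
on a cleverer embedding.

`candidate_fitness()` scores a candidate word against the accepted set:
GC deviation, excess adjacent repeats, a stem indicator, and distance
deficits $\max(0, d - H)$ against every accepted word (plain and, with
RC, reverse-complement distance, plus the self-RC term). The score is 0
exactly on words that may legally join the set.

## Growing a set

How one turns a per-word optimizer into a *set* constructor was an open
design choice; we use sequential greedy extension with plateau escape:

1. run the optimizer (population 30, up to 40 iterations, raised
   mutation probability 0.3, early stop at score 0) to propose a word;
2. accept it only at score exactly 0 — validity is therefore
   unconditional, and the emitted set always passes
   `validate_codeset()`;
3. after `stall_limit = 6` consecutive failed proposals, record the
   incumbent, drop 1–3 random words (with probability
   `big_ruin_prob = 0.2`, a large fraction, 40–80%), and regrow;
4. return the largest set seen over `phases` such cycles.

The plateau-escape step matters: plain greedy growth saturates at
locally maximal sets a few words short of the optimum. With the default
`phases = 40` the search comfortably clears the published size 20 at
$(n, d) = (5, 3)$ under GC+NL; with `phases = 100` it reproduces the
exhaustive maximum (verified against a max-clique oracle) at every
$d$ for $n = 4$. The raised in-search mutation probability reflects the
decode landscape: plateaus of equal score are wide, and the default 0.05
mixes too slowly there. The 500-iteration cap on proposal runs is
enforced as the maximum allowed budget.

```{r search}
cfg <- code_search_config(dna_constraints(n = 4, d = 3), phases = 10,
                          seed = 1)
cs <- construct_code_set(cfg)
cs
validate_codeset(cs)$overall_pass
```

`build_bounds_table()` repeats this per $(n, d)$ cell and attaches
percentage comparisons against the packaged reference bounds
(`ref_lower_bounds()`), which ship as comparison data only: the large-n
published cells are stochastic search artifacts and are not treated as
reproducible truth. All rate and percentage displays use truncation
toward zero, not rounding — the only convention consistent with the
published rate tables (e.g. 0.5804 from 0.58048).

## Benchmark harness

`benchmark_fn()` provides 19 test functions: the seven classic unimodal
problems (F1–F7), six classic multimodal ones (F8–F13), and six
composite functions (F14–F19) built as normalized Gaussian-weighted
mixtures of five shifted components with per-function recorded seeds
(1301–1306) — a reproducible stand-in, since no external reference
rotation data is bundled. `run_experiment()` reports AVG and SD over
repeated runs with per-run seeds derived from one master seed and shared
across algorithms, so comparisons are paired. `rank_sum_test()`
implements the Wilcoxon rank-sum comparison with exact enumeration on
mid-ranks for combined samples up to 12 and a tie- and
continuity-corrected normal approximation beyond; it reports raw
two-sided p-values and leaves significance interpretation to the caller.

## Melting temperatures

`melting_temperature()` implements the unified nearest-neighbor model
(SantaLucia 1998 parameters): stacked dinucleotide $\Delta H/\Delta S$
sums, terminal initiation corrections, a symmetry correction for
self-complementary words, the entropy salt correction
$\Delta S + 0.368\,(n-1)\ln[\mathrm{Na}^+]$, and the concentration term
$R \ln C$ under the primer-in-excess convention ($C$ = primer
concentration). Defaults are 200 nM primer and 50 mM monovalent salt —
the latter deliberately reads an implausible "50 nM salt" operating
condition as millimolar, the only physically sensible unit for a PCR
buffer. At these defaults the 10-mer ACGTATCAGA melts at about 25.3 °C.
`tm_variance()` is the population variance of per-word Tm over a code
set: thermally uniform sets support a single PCR regime, so smaller is
better. Whether RC-constrained sets have systematically lower Tm
variance is an empirical question about specific sets; the package
reports the statistic and does not assert a direction.

## Storage codec

`dna_encode_bytes()` maps each byte to four bases, most-significant bit
pair first (0x1B → ATCG); `dna_decode_bases()` inverts it exactly, and
file-level wrappers move payloads through FASTA. The codec is a raw
payload mapping: it does not thread payloads through constraint-passing
codewords, because connecting the two is an addressing/ECC design of its
own and is deliberately out of scope.

## What the tests do and do not show

The suite checks the constraint predicates against exhaustive and
brute-force oracles at small $n$, the validator against an independent
pairwise checker, the search against a max-clique oracle at $n \le 4$,
the rank-sum test against subset enumeration, and the thermodynamic
model against an independently computed fixed point. Problem sizes in
the stochastic checks (10 seeds at $n = 5$, 30-run optimizer batches)
were chosen as the smallest batches at which the stochastic claims are
stable. None of this certifies behaviour on wet-lab data: the
constraints are the standard proxies for synthesis/sequencing
robustness, the stem screen is not a folding model, and Tm values
inherit the uncertainty of the nearest-neighbor parameter choice.

## Known limitations

* The search is heuristic: large-$n$ published cells are not
  reproducible at desk scale, and the package makes no maximality claims
  beyond brute-force-verified tiny instances.
* Composite benchmark functions are seeded constructions, comparable
  across runs of this package but not bit-compatible with any external
  reference suite.
* IUPAC ambiguity codes and RNA are not supported; words are strict
  A/C/G/T.
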