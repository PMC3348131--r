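# ensemblepockets

Druggable-pocket discovery usually analyses a single, rigid protein
conformer — and misses the transient clefts that open and close as the
protein breathes in solution. `ensemblepockets` implements the
multi-conformer alternative for structural bioinformaticians and
computational drug designers: starting from one structure it

1. **generates a native-like conformational ensemble** by distance-constraint
   sampling — a library of interatomic distance bounds is built from the
   template (covalent bonds tightest, then 1-3 pairs, hydrogen bonds,
   nonbonded contacts), every atom is randomly displaced, and a
   pairwise-projection correction loop restores feasibility; structures
   whose total bound violation exceeds a threshold are rejected;
2. **detects surface pockets on every conformer** with a grid-probe method:
   candidate site points are grid positions outside the van der Waals
   surface whose *enclosure* (fraction of cast rays blocked by protein)
   shows them to be buried; 26-connected clusters of at least 15 site
   points form pockets;
3. **scores druggability**. With `n` the site-point count, `e` the
   enclosure and `p` the hydrophilicity:

   ```
   SiteScore = 0.0733 √min(n,100) + 0.6688 e − 0.20 min(p, 1)
   Dscore    = 0.094  √min(n,100) + 0.60   e − 0.324 p
   ```

   SiteScore ≥ 0.80 marks a drug-binding candidate; values near 1.0
   indicate submicromolar promise. Dscore leaves `p` uncapped to penalise
   highly hydrophilic (hard-to-drug) sites in full;
4. **tracks pocket identity across the ensemble** by geometric-centre
   matching against a labelled reference catalog: ≤ 3.75 Å auto-assigns a
   label (two reference centres within the cutoff merge, e.g. `C_E`),
   3.75–10 Å is flagged *ambiguous* for human review, > 10 Å is *new*;
   per-label *persistence* is the fraction of conformers containing the
   site;
5. **computes per-residue pocket-lining propensities (Provar)**: a residue
   scores 1 in a conformer when any atom lies within 3.75 Å of a pocket
   sphere; the mask mean over the ensemble is written to the B-factor
   column for white-to-red rendering between the first and third
   quartiles of the probability distribution.

Everything is testable offline: deterministic fixture generators
(shell-with-cavity, slab, two-cavity, ideal helix bundle) provide
structures with analytic ground truth.

## Worked example

```r
library(ensemblepockets)

# A 6 Å cavity behind a 60° aperture; analytic volume 763.4 Å³
sh <- make_shell_cavity()
detect_pockets(sh$structure)[, c("n", "volume", "enclosure", "p",
                                 "balance", "site_score", "druggable")]
#>       n volume enclosure     p balance site_score druggable
#> 1   835    835     0.854 0.180    4.57       1.27 TRUE
```

One pocket is found: 835 site points at 1 Å spacing give 835 Å³ (9%
above the analytic volume), mean enclosure 0.854, mostly hydrophobic
character (balance 4.6), and SiteScore 1.27 — well above the 0.80
drug-binding cut-off, as designed for this fixture.

```r
# 25 conformers of a 300-atom helix bundle, tracked against its template
hb  <- make_helix_bundle()$structure
ens <- generate_ensemble(hb, n = 25, seed = 1)
glance(ens)
#>   n_conformers n_attempts max_total_violation mean_ca_rmsd max_ca_rmsd
#> 1           25         25            0.000996        0.460       0.513

ref <- detect_pockets(hb)
cat <- build_catalog(ref, labels = LETTERS[seq_len(nrow(ref))])
tr  <- track_ensemble(detect_ensemble_pockets(ens), cat, n_conformers = 25)
head(tr$persistence, 5)
#>   label n_present persistence
#> 1 A            15        0.60
#> 2 B            13        0.52
#> 3 C            11        0.44
#> 4 D            14        0.56
#> 5 E            10        0.40
```

All 25 conformers satisfy the constraint bounds (max total violation
0.001 Å) and stay within 0.51 Å Cα RMSD of the template, yet the
inter-helix grooves already flicker: the most stable site persists in
60% of conformers, others in under half — exactly the transient
behaviour single-conformer analysis cannot see. `tidy(ens)` returns
per-conformer diagnostics; `plot_persistence()`,
`plot_property_distributions()` and `autoplot()` on a Provar profile
give the standard figures.

A thin command-line front-end wrapping these functions is installed at
`inst/cli/ensemblepockets.R` (subcommands `clean`, `conformers`,
`pockets`, `track`, `provar`, `fixtures`).

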