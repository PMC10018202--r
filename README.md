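# acrydock

Covalent docking and cysteine reactivity profiling for acrylamide adducts.

Acrylamide (ACR), a food-processing by-product and industrial chemical, is
neurotoxic because its α,β-unsaturated carbonyl reacts with cysteine
thiolates of neuronal proteins by Michael addition, leaving a covalent
propionamide adduct (S–CH₂–CH₂–C(=O)NH₂) on the modified sulfur. Which of a
protein's cysteines reacts — and what the adduct does once formed — depends
on the residue's solvent accessibility, its acidity, and the composition of
its microenvironment: nearby His/Asp/Glu can deprotonate the thiol, and
positively charged Lys/Arg stabilise both the thiolate and the enolate-type
intermediate of the addition, then hydrogen-bond the adduct's carbonyl
oxygen.

`acrydock` implements this reasoning as a tested pipeline for structural
bioinformaticians studying electrophile–protein reactivity:

* **Structure handling** — PDB/mmCIF input via bio3d, altloc resolution,
  minimal force-field parameter assignment (packaged charge/LJ/solvation
  table), ideal-geometry polar-hydrogen placement with reactive cysteines
  modelled deprotonated, disulfide detection.
* **Cysteine profiling** — Shrake–Rupley solvent-accessible surface area
  (1.4 Å probe), relative-acidity ranking (annotated pKa or an internal
  heuristic), the deprotonation penalty ln(10)·kT·(pKa − pH), and the 5 Å
  microenvironment census around Sγ.
* **Covalent docking** — the bond is emulated by scaling the Sγ van der
  Waals radius 10-fold and two flat-bottom restraints (Sγ–C 1.8 ± 0.1 Å,
  Cβ–C 2.8 ± 0.1 Å); rigid-body pose generation, Monte-Carlo annealing over
  ligand and side-chain torsions, greedy clustering by interface-ligand
  RMSD (1.0 Å cutoff), and the weighted composite score

  `score = 1.0·Evdw + 0.1·Eelec + 1.0·Edesol + 0.1·Eair`

  with cluster scores averaged over each cluster's four best members. A
  multibody mode docks two adducts onto nearby cysteines simultaneously.
* **Interaction analysis** — hydrogen bonds (donor–acceptor ≤ 4.1 Å,
  donor-H-acceptor ≥ 100°) and hydrophobic contacts (apolar carbons,
  |q| < 0.15 e, ≤ 4.0 Å), cluster-size-weighted frequencies split by the
  adduct's carbonyl vs amino group, and per-site reaction-context reports.
* **Site ranking** — within-protein comparison of analysed-cluster scores,
  primary/secondary site designation, conformational-state comparison, and
  TSV/JSON/Markdown reports. Scores are arbitrary units, comparable only
  within one protein and one configuration.
* **Synthetic pockets** — a fully self-contained generator of mini-protein
  grooves with a planted reactive cysteine and controllable
  microenvironments (Lys/Arg, Ala, Asp/Glu, or His flanks; planted
  hydrogen-bond geometry), so the entire pipeline is testable offline.

## Worked example

Dock the adduct onto the cysteine of a synthetic Lys-lined pocket and
inspect the result:

```r
library(acrydock)

s <- generate_pocket(pocket_spec("helix-pair", "positive", n_flank = 2, seed = 1))
cys <- attr(s, "pocket_info")$cys                    # chain A, residue 29

cfg <- dock_config(n_initial = 150, n_selected = 40,
                   anneal_steps = c(70, 70), seed = 1)
res <- dock_site(s, cys, cfg)
res
#> Covalent docking result for A:29
#>   40 refined poses in 14 cluster(s); 2 analyzed
#>   cluster 1: score    -9.00 a.u. (sd 0.14), size 8 *
#>   cluster 2: score    -8.93 a.u. (sd 0.00), size 1 *
#>   cluster 3: score    -8.70 a.u. (sd 0.41), size 4
#>   ...
covalent_bond_formed(res)
#> [1] TRUE
```

The top cluster's score of −9.00 arbitrary units is the mean composite of
its four best members; the second cluster lies within the top cluster's
spread and is analysed too. The covalent-bond check confirms the
representative satisfies both distance restraints within three times their
tolerance. Fingerprinting the analysed clusters gives cluster-size-weighted
interaction frequencies:

```r
fp <- fingerprint_result(res)
fp[, c("partner_resno", "partner_restype", "type", "ligand_group", "frequency")]
#>   partner_resno partner_restype        type ligand_group frequency
#> 1            10             LEU hydrophobic         none     100.0
#> 2            29             CYS hydrophobic         none     100.0
#> 3            32             VAL hydrophobic         none     100.0
#> 4            33             VAL hydrophobic         none      22.2
#> 5            32             VAL       hbond        amino      11.1
```

In this run the adduct packs its methylene carbons against the groove
(every analysed pose contacts Leu10 and the wall carbons) while the amide
occasionally donates to a backbone oxygen; across seeds the planted
lysines win on average, which is what the ten-seed discrimination
experiment quantifies.

Within-protein site ranking on reported per-site scores (packaged registry):

```r
reg <- acr_target_registry()
ck  <- reg[reg$protein_id == "CK", ]
rank_sites(data.frame(site = ck$site, score = ck$score_au,
                      size = ck$top_cluster_size, covalent = ck$covalent),
           protein = "Creatine Kinase")
#> Site ranking (Creatine Kinase)
#>  site score size covalent                    role
#>  C283 -32.8   61     TRUE                 primary
#>  C141 -31.7   63     TRUE               secondary
#>  C146 -28.2   22     TRUE               secondary
#>  C254 -23.3   34     TRUE                   other
#>   C74 -21.3   12    FALSE no covalent bond formed
```

C283, the experimentally established primary modification site, ranks
first; C141/C146 fall inside the secondary-site window; C74's top cluster
never formed the covalent bond and is excluded from primary designation.

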