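#!/usr/bin/env Rscript
# Variant preselection from the WGS panel: the multi-line GWAS stand-in on
# the training set, then the five panel constructions (Top40k, TopSign,
# ChipPlusSign, LDTags, AllComb) with the chip as baseline.

library(mlgblup)

dir.create("results", showWarnings = FALSE)
sim <- simulate_population(sim_config(seed = 2024))

sp <- make_split(sim$ped, sim$geno_wgs$ids, split_spec())
cat(sprintf("training %d, test %d animals\n",
            length(sp$training), length(sp$test)))

disc <- subset_genotypes(sim$geno_wgs, ids = sp$training)
gw <- run_gwas(disc, sim$pheno, "trait", test_ids = sp$test)
cat(sprintf("GWAS: %d markers scanned, %d at p <= 1e-6\n",
            nrow(gw), sum(gw$p <= 1e-6)))
write.table(gw, "results/03_gwas.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

panels <- build_panels(sim$geno_chip$map$marker, list(gw), sim$geno_wgs)
sizes <- data.frame(panel = names(panels),
                    n_markers = sapply(panels, length))
write.csv(sizes, "results/03_panel_sizes.csv", row.names = FALSE)
print(sizes)

# how often do preselected panels capture markers near true QTL?
qtl <- sim$truth$qtl
map <- sim$geno_wgs$map
near_qtl <- function(markers, window = 55000) {
  pos <- map[match(markers, map$marker), ]
  mean(sapply(seq_len(nrow(qtl)), function(k) {
    q <- map[match(qtl$marker[k], map$marker), ]
    any(pos$chrom == q$chrom & abs(pos$pos - q$pos) <= window)
  }))
}
cover <- data.frame(panel = names(panels),
                    qtl_coverage = round(sapply(panels, near_qtl), 3))
write.csv(cover, "results/03_qtl_coverage.csv", row.names = FALSE)
print(cover)
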