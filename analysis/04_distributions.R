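#!/usr/bin/env Rscript
# Stage 4: distribution-level comparisons of per-species smallest / mean /
# largest reported sizes (KS, centered-variance F, Spearman), their ECDFs,
# and the intra- vs interspecific range contrast across the taxonomic
# hierarchy (using the most diverse phylum as the exemplar clade).

suppressPackageStartupMessages(library(sizerange))

dat <- read_summaries("results/species_summaries.csv")

dist <- compare_size_distributions(dat)
readr::write_csv(dist, "results/distribution_tests.csv")
cat("smallest / mean / largest distribution comparisons:\n")
print(as.data.frame(dist), digits = 4)

ecdfs <- dplyr::bind_rows(lapply(
  c(minimum = "log10_smallest", mean = "log10_mean", maximum = "log10_largest"),
  function(col) ecdf_table(dat[[col]])), .id = "metric")
readr::write_csv(ecdfs, "results/size_ecdfs.csv")

# exemplar clade: the phylum with the most retained species
exemplar <- names(which.max(table(dat$phylum)))
sub <- dat[dat$phylum == exemplar, ]
hier <- dplyr::bind_rows(lapply(c("order", "family", "genus", "species"),
  function(lv) taxon_interspecific_ranges(sub, level = lv)))
readr::write_csv(hier, "results/taxon_ranges.csv")
cat(sprintf("\nexemplar clade %s: mean range by level\n", exemplar))
print(aggregate(range ~ level, hier, mean), digits = 3)
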