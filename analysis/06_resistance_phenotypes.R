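#!/usr/bin/env Rscript
# Herbicide-injury phenotype tabulation: per-plant injury scores are binned
# (High 0-32, Moderate 33-67, Susceptible 68-100; samples with both
# resistant and dead plants are Segregating) and tabulated by field
# cropping history. Writes results/resistance/resistance_table.tsv.

suppressMessages(library(weedhyb))

out <- "results/resistance"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

inj <- read_injury_tsv(system.file("extdata", "table2_injury_synthetic.tsv",
                                   package = "weedhyb"))
tab <- tabulate_resistance(inj)
write.table(cbind(Resistance = rownames(tab$table), tab$table),
            file.path(out, "resistance_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("resistance levels by field cropping history (count (%)):\n")
print(tab$table, quote = FALSE)
any_res <- sum(tab$counts[c("High", "Moderate", "Segregating"), "Total"]) /
  sum(tab$counts[, "Total"]) * 100
cat(sprintf("samples with some degree of resistance: %.1f%%\n", any_res))
cat("written:", out, "\n")
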