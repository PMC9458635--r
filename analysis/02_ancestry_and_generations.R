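#!/usr/bin/env Rscript
# From the simulated cohort VCF: discover ancestry-informative markers
# between the two panels, compute supervised ancestry coefficients for the
# contemporary samples, and date each hybridization event from the decay of
# AIM heterozygosity under selfing. Writes results/ancestry/*.tsv.

suppressMessages(library(weedhyb))

gm <- read_vcf("results/simulated/cohort.vcf")
panels <- read_panels("results/simulated/panels.tsv", gm)
out <- "results/ancestry"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

crop <- subset_gm(gm, panels$sample_id[panels$panel == "crop"])
weed <- subset_gm(gm, panels$sample_id[panels$panel == "weed"])
aims <- identify_aims(crop, weed)
cat("AIMs discovered:", nrow(aims), "fixed differences\n")
write.table(as.data.frame(aims), file.path(out, "aims.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

contemp <- panels$sample_id[panels$panel == "contemporary"]
cgm <- subset_gm(gm, contemp)
anc <- supervised_ancestry(cgm, aims, pop_names = c("crop", "weed"))
write.table(anc, file.path(out, "ancestry_coefficients.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean crop ancestry coefficient %.3f (range %.3f-%.3f)\n",
            mean(anc$crop), min(anc$crop), max(anc$crop)))

gens <- do.call(rbind, lapply(contemp, function(s) {
  h <- aim_heterozygosity(cgm, s, aims)
  e <- estimate_generations(h$fraction, h$n_called)
  data.frame(sample_id = s, n_het = h$n_het, n_called = h$n_called,
             het_fraction = h$fraction, g_hat = e$g_hat, g_lo = e$ci[1],
             g_hi = e$ci[2], censored = e$censored)
}))
write.table(gens, file.path(out, "generation_estimates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
est <- gens$g_hat[!gens$censored]
cat(sprintf("generations since hybridization: median %.2f, %d/%d censored (zero het)\n",
            median(est), sum(gens$censored), nrow(gens)))
cat("written:", out, "\n")
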