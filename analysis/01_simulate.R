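#!/usr/bin/env Rscript
# Stage 1 -- simulate the hologenome dataset.
#
# Generates the study-condition dataset (genotypes with block LD, the
# two-nitrogen split-plot field design, partly heritable ASV abundances,
# and a phenotype with LN-only microbial effects), reports what was planted,
# and writes the tables plus the ground-truth sidecar under results/data/.

source(file.path("analysis", "_common.R"))

ds <- study_dataset()
holo <- ds$holo

out <- file.path(RESULTS_DIR, "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_geno_tsv(holo$geno, file.path(out, "genotypes.tsv"))
write_geno_vcf(subset_markers(holo$geno, 1:200),
               file.path(out, "genotypes_head200.vcf"))
write_microbiome_tsv(holo$microbiome, file.path(out, "microbiome.tsv"))
write.csv(cbind(holo$design, y = unname(holo$phenotype)),
          file.path(out, "phenotype_design.csv"), row.names = FALSE)
write_truth_json(holo$truth, file.path(out, "truth.json"))

cat(sprintf("simulated %d genotypes x %d SNPs; %d plots retained of %d\n",
            nrow(holo$geno$dosages), ncol(holo$geno$dosages),
            nrow(holo$design),
            holo$config$n_genotypes * holo$config$n_treatments *
              holo$config$n_blocks))
cat(sprintf("%d ASVs (%d groups, %d classes); %d heritable, %d causal, %d mediators\n",
            ncol(holo$microbiome$values),
            length(unique(holo$microbiome$taxonomy$group)),
            length(unique(holo$microbiome$taxonomy$class)),
            length(holo$truth$heritable_ids),
            length(holo$truth$causal_ids),
            length(holo$truth$mediator_ids)))
comp <- holo$truth$components
tot <- var(comp$genetic) + var(comp$microbial) + var(comp$residual)
cat(sprintf("realized variance shares: SNP %.3f, ASV %.3f (LN-only), residual %.3f\n",
            var(comp$genetic) / tot, var(comp$microbial) / tot,
            var(comp$residual) / tot))
cat("wrote", out, "\n")
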