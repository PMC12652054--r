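#!/usr/bin/env Rscript
# Stage 5: torsional parameterization. Fits CHARMM-style cosine-series
# dihedral terms (nonnegative force constants, phases 0/180, per-scan
# offsets) jointly to the five N-methoxy-linker energy scans and writes
# the fitted parameters as JSON and as a CHARMM parameter stream.

suppressPackageStartupMessages(library(ctsbind))
dat <- "results/data"; out <- "results"

profiles <- read_dihedral_profiles(file.path(dat, "torsion_scans.tsv"))
fit <- fit_dihedral_terms(profiles)
cat(sprintf("Fitted %d dihedrals over %d grid points; pooled RMSE %.3f kcal/mol\n",
            length(fit$term_set$terms),
            sum(vapply(profiles, function(p) length(p$angles), 0L)),
            fit$rmse))
print(fit)

jsonlite::write_json(list(rmse = fit$rmse, terms = fit$term_set$terms,
                          offsets = as.list(fit$term_set$offsets)),
                     file.path(out, "dihedral_fit.json"),
                     auto_unbox = TRUE, pretty = TRUE)
write_charmm_dihedrals(fit$term_set, file.path(out, "dihedral_fit.str"))
cat("CHARMM stream written to results/dihedral_fit.str\n")
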