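#!/usr/bin/env Rscript
# Two-cleavage-site polypeptide: search transport-parameter space for the
# four cleavage-site-usage behaviour classes and demonstrate that usage
# drifts over time even with product re-entry disabled — i.e. transport
# properties alone explain changing cleavage-site usage.

library(proteodyn)

out_dir <- file.path("results", "05_polypeptide")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1

fs <- fragment_set()
message("Sampling transport parameters and classifying usage behaviour...")
sb <- search_behaviors(fs, prior = default_poly_prior(fs, orders = 3),
                       n_samples = 4000, seed = seed)
print(sb$frequencies)
utils::write.csv(data.frame(label = names(sb$frequencies),
                            count = as.integer(sb$frequencies)),
                 file.path(out_dir, "behavior_frequencies.csv"),
                 row.names = FALSE)
for (lab in names(sb$exemplars))
  jsonlite::write_json(as.list(sb$exemplars[[lab]]),
                       file.path(out_dir, paste0("exemplar_", lab, ".json")),
                       auto_unbox = TRUE, digits = NA)

message("Usage drift without product re-entry:")
fs2 <- fs
fs2$transport$BC[c("tau", "vout")] <- c(0.02, 0.05)   # retain BC inside
fs2$transport$AB[c("tau", "vout")] <- c(30, 10)       # flush AB
tr <- simulate_polypeptide(build_polypeptide_model(fs2), 50,
                           seq(10, 240, 10), product_reentry = FALSE)
u <- cleavage_site_usage(tr)
utils::write.csv(u, file.path(out_dir, "usage_no_reentry.csv"),
                 row.names = FALSE)
message(sprintf("  site-2 share of cleavage moves from %.2f to %.2f; class: %s",
                u$rel_site2[2], utils::tail(u$rel_site2, 1),
                classify_usage_behavior(u)))

ml <- mean_fragment_length(tr)
message(sprintf("  mean product length %.1f -> %.1f residues",
                ml[2], utils::tail(ml, 1)))
message("Done; outputs under ", out_dir)
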