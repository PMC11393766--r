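#!/usr/bin/env Rscript
# Validation of the allometric dispersal worked example against the three
# published distances (brown-eared bulbul 39.7 km, Japanese wood pigeon
# 88.8 km, jungle crow 110 km).
#
# The original allometric regression coefficients are not printed in the
# study; the bundled config uses the flight-scaling exponent (1/6) with the
# remaining coefficients calibrated against the published distances (see
# inst/extdata/allometry_birds.yaml).  Exact 3-significant-figure agreement
# therefore requires transcribing the coefficients from the cited sources
# and substituting them via --config.
#
#   Rscript scripts/dispersal_validation.R [--config path.yaml] [--species path.tsv]

suppressMessages(library(coalSFS))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
cfg <- getArg("--config",
              system.file("extdata", "allometry_birds.yaml", package = "coalSFS"))
species <- getArg("--species",
                  system.file("extdata", "disperser_birds.tsv", package = "coalSFS"))

tab <- dispersalTable(species, readAllometryConfig(cfg))
published <- c(39.7, 88.8, 110)
tab$published_km <- published[seq_len(nrow(tab))]
tab$rel_diff_pct <- round(100 * (tab$distance_km / tab$published_km - 1), 2)
print(tab, digits = 4)
cat("\nmax |relative difference|:", max(abs(tab$rel_diff_pct)), "%\n")
ok <- all(signif(tab$distance_km, 3) == signif(tab$published_km, 3))
cat(if (ok) "all three distances match to 3 significant figures\n" else
  "distances do not all match to 3 significant figures (see header note)\n")
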