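#!/usr/bin/env Rscript
# Stage 2: construct the analyzed traits from the raw collection records.
#
# Collections are spread into daily production (discarding biologically
# impossible >= 3 eggs/day records for individually housed hens), summed
# into weekly production on the age scale, expressed as deviations from
# the batch average, and condensed into one row per hen/cage: EP (total
# eggs, weeks 25-83), LNVAR, SKEW and AUTO-R of the weekly deviations.
# Outliers beyond 4 SD within a population are discarded per indicator.

library(resilayer)

inp <- "results/data"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

records  <- read.csv(file.path(inp, "records.csv"))
metadata <- read.csv(file.path(inp, "metadata.csv"))
members  <- read.csv(file.path(inp, "members.csv"))

is_hen <- records$unit_type == "hen"
tab_p <- construct_traits(records[is_hen, ],
                          metadata[metadata$unit_type == "hen", ],
                          population = "purebred")
tab_c <- construct_traits(records[!is_hen, ],
                          metadata[metadata$unit_type == "cage", ],
                          members = members, population = "crossbred")
tab <- rbind(tab_p, tab_c)
write.csv(tab, "results/trait_table.csv", row.names = FALSE)

summ <- do.call(rbind, lapply(split(tab, tab$population), function(d)
  data.frame(population = d$population[1],
             trait = c("EP", "LNVAR", "SKEW", "AUTO_R"),
             mean = sapply(d[c("EP", "LNVAR", "SKEW", "AUTO_R")], mean,
                           na.rm = TRUE),
             sd = sapply(d[c("EP", "LNVAR", "SKEW", "AUTO_R")], sd,
                         na.rm = TRUE))))
write.csv(summ, "results/tables/phenotype_summary.csv", row.names = FALSE)

cat("Trait table:", nrow(tab_p), "purebred hens,", nrow(tab_c),
    "crossbred cages.\n")
cat("Outlier removal fractions (purebred):\n")
print(attr(tab_p, "removed"))
cat("\nPhenotypic means and SDs:\n")
print(summ, row.names = FALSE, digits = 3)
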