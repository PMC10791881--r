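#!/usr/bin/env Rscript
# Generate the reference synthetic city and its monitoring campaign
# design, and write every layer to plain-text GIS formats under
# results/city/. The city emulates the structure of the study setting:
# a projected-metric urban extent with categorical land use, a classed
# road grid, population and altitude rasters, and a small met network;
# 40 monitoring sites are spread over the samplable area, stratified by
# traffic / residential / industrial character plus one urban background
# site.

library(urbanlur)

seed <- 101
city <- generate_city(seed = seed)
sites <- generate_sites(city, n_sites = 40, seed = seed + 1L)

dir.create("results", showWarnings = FALSE)
files <- write_city(city, "results/city")
write.csv(sites, "results/city/sites.csv", row.names = FALSE)

print(city)
cat("land-use mix at the 40 sites:\n")
print(table(landuse_at(city, sites$x, sites$y)))
cat("site strata:\n")
print(table(sites$stratum))
cat("road network:", nrow(city$roads), "segments;",
    sum(city$roads$class %in% c("TRUNK", "PRIM")), "major\n")
cat("layers written to results/city/:",
    paste(basename(files), collapse = ", "), "\n")
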