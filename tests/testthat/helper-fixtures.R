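# Shared in-code fixtures: a single small chromosome and hand-laid marker
# maps/tracks used across the unit tests.

one_chrom_layout <- function(len = 10000, cen = c(4500, 4600),
                             mask = 0) {
  genome_layout("chrI", len, cen[1], cen[2],
                mask_left = mask, mask_right = mask)
}

mk_map <- function(pos, chrom = "chrI") {
  n <- length(pos)
  marker_map(tibble::tibble(chrom = chrom, pos = pos,
                            allele1 = rep("A", n), allele2 = rep("T", n)))
}

mk_track <- function(map, genotype, clone = "c1") {
  tibble::tibble(clone = clone, chrom = map$chrom, pos = map$pos,
                 genotype = genotype)
}

# Layout/map/hotspots triple for simulator-scale tests (kept small).
sim_fixture <- function(n_chrom = 2, chrom_length = 400000, theta = 0.002,
                        seed = 42) {
  layout <- toy_layout(n_chrom, chrom_length)
  map <- simulate_marker_map(layout, theta, seed = seed)
  hs <- simulate_hotspots(layout, n_per_chrom = 20, seed = seed + 1)
  list(layout = layout, map = map, hotspots = hs)
}
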