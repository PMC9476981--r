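# shared fixtures for the suite

CLASS_COLS <- c("2C", "4C", "8C", "16C", "32C", "64C")

# class-percentage row of the published reference table for one species/organ
ref_row <- function(species, organ) {
  tab <- pulmonaria_class_proportions()
  r <- tab[tab$species == species & tab$organ == organ, ]
  stopifnot(nrow(r) == 1)
  stats::setNames(as.numeric(r[, CLASS_COLS]), CLASS_COLS)
}

ref_params <- function(species, organ) {
  tab <- pulmonaria_endopoly_params()
  tab[tab$species == species & tab$organ == organ, ]
}

# independent oracle for gating: nearest assigned-peak position in log space
nearest_peak_oracle <- function(intensities, positions, c_levels) {
  d <- abs(outer(log(intensities), log(positions), "-"))
  cls <- c_levels[apply(d, 1, which.min)]
  counts <- vapply(sort(unique(c_levels)), function(l) sum(cls == l),
                   numeric(1))
  stats::setNames(counts, paste0(sort(unique(c_levels)), "C"))
}

# a small genome-size measurement table: three plants x three runs per species
make_gs_table <- function(ratios = c("P. mollis" = 1.620,
                                     "P. murinii" = 1.179),
                          noise_sd = 0.002, std_mean = 200) {
  rows <- list()
  for (sp in names(ratios)) {
    for (plant in 1:3) {
      for (rep_i in 1:3) {
        r <- ratios[[sp]] * (1 + stats::rnorm(1, 0, noise_sd))
        rows[[length(rows) + 1]] <- data.frame(
          Species = sp, Plant = paste0("pl", plant), Repetition = rep_i,
          Area_std = 5200, Mean_std = std_mean, CV_std = 3.0,
          Area_sample = 5200, Mean_sample = std_mean * r, CV_sample = 3.0,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
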