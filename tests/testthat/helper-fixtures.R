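# shared fixtures built in code

# hydrophobic surface-pocket residues used across NMR fixtures
pocket_residues <- c("W65", "V84", "F85", "V86", "G116", "K118", "G119",
                     "A120")

# a flat-background image with 5 bars (20 x 3 px) and 3 disks (r = 5 px)
constructed_bar_disk_image <- function(bg = 10, fg = 100, dim = 200) {
  img <- matrix(bg, dim, dim)
  bar_pos <- cbind(c(30, 70, 110, 150, 170), c(30, 80, 130, 60, 160))
  for (i in seq_len(nrow(bar_pos))) {
    img[bar_pos[i, 1] + (0:2), bar_pos[i, 2] + (0:19)] <- fg
  }
  disk_ctr <- list(c(40, 170), c(100, 40), c(170, 100))
  for (ctr in disk_ctr) {
    for (r in -5:5) for (cc in -5:5) {
      if (r^2 + cc^2 <= 25) img[ctr[1] + r, ctr[2] + cc] <- fg
    }
  }
  img
}

# a peak table whose pocket residues are displaced by `pocket_shift` ppm
# in 1H against a quiet background
shifted_peak_tables <- function(pocket_shift, background_shift = 0.001,
                                n_background = 12, seed = 42) {
  residues <- c(pocket_residues, paste0("B", seq_len(n_background)))
  set.seed(seed)
  apo <- peak_table(residues, runif(length(residues), 7, 9.5),
                    runif(length(residues), 105, 130), "apo")
  bound <- apo
  shift <- ifelse(residues %in% pocket_residues, pocket_shift,
                  background_shift)
  bound$dH_ppm <- bound$dH_ppm + shift
  bound$condition_id <- "bound"
  list(apo = apo, bound = bound)
}
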