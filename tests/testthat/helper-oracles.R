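# Independent brute-force oracle for composition search: enumerates every
# count vector by expand.grid and filters by vectorized mass arithmetic,
# sharing no code with enumerate_compositions().
brute_force_compositions <- function(mz, tol, max_residues = 8) {
  mm <- residue_masses()
  grid <- expand.grid(h = 0:max_residues, p = 0:max_residues,
                      d = 0:max_residues, u = 0:max_residues,
                      m = 0:max_residues, a = 0:max_residues)
  grid <- grid[rowSums(grid[, c("h", "p", "d", "u")]) >= 1 &
                 rowSums(grid[, c("h", "p", "d", "u")]) <= max_residues &
                 grid$m <= grid$u &
                 grid$a <= grid$h + grid$p &
                 grid$u <= grid$h + grid$p, ]
  mass <- grid$h * mm[["hexose"]] + grid$p * mm[["pentose"]] +
    grid$d * mm[["deoxyhexose"]] + grid$u * mm[["hexuronic_acid"]] +
    grid$m * mm[["methyl"]] + grid$a * mm[["acetyl"]] +
    mm[["water"]] + mm[["sodium"]]
  hit <- grid[abs(mass - mz) <= tol, ]
  # canonical string key set for comparison
  sort(apply(hit, 1, paste, collapse = ","))
}

comp_key <- function(comp) {
  paste(comp[["n_hex"]], comp[["n_pen"]], comp[["n_dhex"]], comp[["n_hexa"]],
        comp[["n_methyl"]], comp[["n_acetyl"]], sep = ",")
}

# All composition codes annotated with a printed nominal m/z in the apple
# digests (the xyloglucan typo XLGa1/1451 is excluded; see the acceptance
# tests, where it is asserted to conflict with the letter grammar).
printed_ions <- function() {
  vapply(c(Hex4a1 = 731, Hex4a2 = 773, Hex5a1 = 893, Hex5a2 = 935, Hex6a1 = 1055,
    Hex4 = 689, Hex5 = 851, Hex7a1 = 1217, Hex7a2 = 1259, Hex8a1 = 1379,
    Hex8a2 = 1421, Hex3a1 = 569, Pen4 = 569, Pen3U1 = 613, Pen3U1a1 = 655,
    Pen4a1 = 611, Pen4a2 = 653, Pen4U1m1 = 759, Pen4U1m1a1 = 801,
    Pen5a1 = 743, Pen5U1m1a1 = 933, XXXG = 1085, XXFGa1 = 1435,
    XLFGa1 = 1597, XXG = 791, XLG = 953, GFG = 967, XFG = 1099,
    XLXG = 1247, XLXGa1 = 1289, XXFG = 1393, XXFGa2 = 1477, XLFGa2 = 1639),
    as.integer, 0L)
}

write_peaklist_file <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
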