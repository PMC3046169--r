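# Shared fixtures and independent oracles. The oracles restate the energy
# formulas and metric definitions from scratch (no calls into the package's
# region machinery) so that agreement is a genuine cross-check.

# ---- fixtures ----------------------------------------------------------

fix_toy <- function(seed = 42, planted1 = 3, separation = 9.5) {
  spec <- toy_complex_spec("KRELWS", "DEYKLS", separation = separation,
                           planted1 = planted1, seed = seed)
  generate_toy_complex(spec)
}

fix_complex <- function(seed = 42, ...) {
  tc <- fix_toy(seed = seed, ...)
  read_complex(tc$pdb, "A", "B")
}

# random parameterized atom cloud as an hspred_complex (two sides)
random_complex <- function(n, seed, box = 12) {
  set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n), name = "X", element = "C", resname = "UNK",
    chain = rep(c("A", "B"), length.out = n),
    resno = as.character(seq_len(n)), resno_num = seq_len(n),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    side = rep(c(1L, 2L), length.out = n),
    vdw_rmin = runif(n, 1.6, 2.3), vdw_epsilon = runif(n, 0.02, 0.45),
    partial_charge = round(runif(n, -0.8, 0.8), 2),
    solv_dG_free = runif(n, -10, 2), solv_lambda = runif(n, 3, 6),
    solv_volume = runif(n, 4, 24),
    is_donor_heavy = runif(n) < 0.3, is_acceptor = runif(n) < 0.3,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, side1 = "A", side2 = "B"),
            class = "hspred_complex")
}

# construct a site record for a residue of a parsed complex
make_site <- function(cx, chain, resno) {
  a <- cx$atoms
  cb <- a[a$chain == chain & a$resno == as.character(resno) &
            a$name == "CB", ]
  stopifnot(nrow(cb) == 1)
  list(chain = chain, resno = as.character(resno),
       wt = aa_three_to_one(cb$resname),
       cbx = cb$x, cby = cb$y, cbz = cb$z)
}

# ---- independent energy oracle ----------------------------------------
# per-term formulas restated; loops over rows of set A, vectorized over B

oracle_region_energy <- function(cx, idxA, idxB, term,
                                 cfg = energy_config()) {
  A <- cx$atoms[idxA, , drop = FALSE]
  B <- cx$atoms[idxB, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(A))) {
    r <- sqrt((A$x[i] - B$x)^2 + (A$y[i] - B$y)^2 + (A$z[i] - B$z)^2)
    e <- switch(term,
      vdw = {
        eps <- sqrt(A$vdw_epsilon[i] * B$vdw_epsilon)
        rm <- A$vdw_rmin[i] + B$vdw_rmin
        pmin(eps * ((rm / r)^12 - 2 * (rm / r)^6), cfg$lj_cap)
      },
      hbond = {
        hb <- ifelse(r > cfg$hb_rmin & r <= cfg$hb_rmax,
                     cfg$hb_eps * (5 * (cfg$hb_r0 / r)^12 -
                                     6 * (cfg$hb_r0 / r)^10), 0)
        hb * ((A$is_donor_heavy[i] & B$is_acceptor) +
                (B$is_donor_heavy & A$is_acceptor[i]))
      },
      coulomb = cfg$coulomb_k * A$partial_charge[i] * B$partial_charge /
        (cfg$dielectric_slope * r^2),
      desolv = {
        g <- function(dg, lam, rmin, vol, r)
          dg / (2 * pi^1.5 * lam * r^2) * exp(-((r - rmin) / lam)^2) * vol
        ifelse(r <= cfg$desolv_cutoff,
               -(g(A$solv_dG_free[i], A$solv_lambda[i], A$vdw_rmin[i],
                   B$solv_volume, r) +
                   g(B$solv_dG_free, B$solv_lambda, B$vdw_rmin,
                     A$solv_volume[i], r)), 0)
      })
    total <- total + sum(e)
  }
  total
}

# monolithic recomputation of the 12 features from membership predicates,
# never using partition_regions/region_energy
oracle_energy_vector <- function(cx, site, shell = 10,
                                 cfg = energy_config()) {
  a <- cx$atoms
  d2cb <- (a$x - site$cbx)^2 + (a$y - site$cby)^2 + (a$z - site$cbz)^2
  own <- a$chain == site$chain & a$resno == site$resno
  side <- a$side[which(own)[1]]
  in_a <- own & !a$name %in% c("N", "CA", "C", "O", "CB")
  in_b <- d2cb <= shell^2 & a$side == side & !own
  in_c <- d2cb <= shell^2 & a$side != side
  out <- numeric(0)
  for (pair in list(c("a", "c"), c("b", "c"), c("a", "b")))
    for (t in c("vdw", "hbond", "coulomb", "desolv"))
      out <- c(out, oracle_region_energy(
        cx, which(list(a = in_a, b = in_b, c = in_c)[[pair[1]]]),
        which(list(a = in_a, b = in_b, c = in_c)[[pair[2]]]), t, cfg))
  names(out) <- feature_names()
  out
}

# ---- misc oracles ------------------------------------------------------

oracle_metrics <- function(tp, fp, fn, tn) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  m <- ifelse(den > 0, (tp * tn - fp * fn) / den, 0)
  c(precision = p, recall = r, f1 = f1, mcc = m)
}

# brute-force powerset filtering for subset enumeration
oracle_subsets <- function(base, excluded, sizes, extra = NULL) {
  bad_pair <- function(s) {
    if (nrow(excluded) == 0 || length(s) < 2) return(FALSE)
    for (k in seq_len(nrow(excluded)))
      if (excluded$f1[k] %in% s && excluded$f2[k] %in% s) return(TRUE)
    FALSE
  }
  out <- character(0)
  for (sz in sizes) {
    if (sz > length(base)) next
    for (s in utils::combn(base, sz, simplify = FALSE)) {
      if (bad_pair(s)) next
      out <- c(out, paste(sort(s), collapse = "|"))
      if (!is.null(extra))
        out <- c(out, paste(sort(c(s, extra)), collapse = "|"))
    }
  }
  unique(out)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# random rigid-body transform applied to a complex
rigid_transform <- function(cx, seed) {
  set.seed(seed)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  t0 <- rnorm(3, sd = 20)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(M)
  cx$atoms$x <- xyz[, 1] + t0[1]
  cx$atoms$y <- xyz[, 2] + t0[2]
  cx$atoms$z <- xyz[, 3] + t0[3]
  cx
}

small_training_config <- function(seed = 1)
  training_config(C_grid = c(0.1, 1, 10), class_weight_grid = c(1, 2),
                  seed = seed)
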