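atom <- function(x = 0, y = 0, z = 0, rmin = 1.8, eps = 0.1, q = 0,
                 dg = 0, lam = 3.5, vol = 0, donor = FALSE,
                 acceptor = FALSE) {
  list(x = x, y = y, z = z, vdw_rmin = rmin, vdw_epsilon = eps,
       partial_charge = q, solv_dG_free = dg, solv_lambda = lam,
       solv_volume = vol, is_donor_heavy = donor, is_acceptor = acceptor)
}

test_that("Lennard-Jones pair term has the 12-6 shape", {
  i <- atom(0, 0, 0); j <- atom(3.6, 0, 0)
  expect_equal(lj_pair(i, j), -0.1)              # minimum at rmin sum
  j$x <- 3.0
  expect_equal(lj_pair(i, j), 0.2944132448256)    # frozen hand evaluation
  j$x <- 3 * 3.6                                  # long range decay
  expect_lt(abs(lj_pair(i, j)), 0.01 * 0.1)
  j$x <- 0.5                                      # clash capped
  expect_equal(lj_pair(i, j), energy_config()$lj_cap)
  j$x <- 0
  expect_error(lj_pair(i, j), "zero")
})

test_that("hydrogen-bond pair term is a windowed 12-10 potential", {
  d <- atom(0, 0, 0, donor = TRUE); a <- atom(2.9, 0, 0, acceptor = TRUE)
  expect_equal(hbond_pair(d, a), -2.0)            # minimum at r0
  a$x <- 3.2
  expect_equal(hbond_pair(d, a), -1.41510297467695, tolerance = 1e-12)
  a$x <- 4.0
  expect_equal(hbond_pair(d, a), 0)               # beyond cutoff
  a$x <- 2.9
  expect_equal(hbond_pair(atom(0, 0, 0), a), 0)   # non-donor contributes 0
})

test_that("Coulomb pair term follows the distance-dependent dielectric", {
  i <- atom(q = 0.5); j <- atom(3, 0, 0, q = 0.5)
  expect_equal(coulomb_pair(i, j), 2.30599791666667, tolerance = 1e-12)
  expect_equal(coulomb_pair(atom(q = 0), j), 0)
  jneg <- atom(3, 0, 0, q = -0.5)
  expect_lt(coulomb_pair(i, jneg), 0)
  expect_gt(coulomb_pair(atom(q = -0.5), jneg), 0)
})

test_that("desolvation pair term is a symmetric Gaussian exclusion", {
  i <- atom(rmin = 1.7, dg = -5.33, vol = 10.8)
  j <- atom(3.5, 0, 0, rmin = 2.01, dg = 0.52, vol = 22.4)
  expect_equal(desolv_pair(i, j), 0.182121027642937, tolerance = 1e-12)
  expect_equal(desolv_pair(i, j), desolv_pair(j, i))
  expect_equal(desolv_pair(atom(vol = 0), atom(3, 0, 0, vol = 0)), 0)
  j$x <- 10.0
  expect_equal(desolv_pair(i, j), 0)              # beyond cutoff
})

test_that("region_energy equals the brute-force double loop", {
  for (seed in 1:20) {
    cx <- random_complex(sample(10:40, 1), seed)
    n <- nrow(cx$atoms)
    A <- sample(n, n %/% 3); B <- setdiff(sample(n, n %/% 2), A)
    for (t in c("vdw", "hbond", "coulomb", "desolv")) {
      expect_equal(region_energy(cx, A, B, t),
                   oracle_region_energy(cx, A, B, t), tolerance = 1e-11)
      expect_equal(region_energy(cx, A, B, t), region_energy(cx, B, A, t))
    }
  }
})

test_that("region_energy guards its preconditions", {
  cx <- random_complex(20, 1)
  expect_equal(region_energy(cx, integer(0), 1:5, "vdw"), 0)
  expect_equal(region_energy(cx, 1:5, integer(0), "coulomb"), 0)
  expect_error(region_energy(cx, 1:5, 4:8, "vdw"), "overlap")
})

test_that("partition_regions matches brute-force membership predicates", {
  cx <- fix_complex()
  sites <- find_interface_residues(cx)
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    reg <- partition_regions(cx, site, 10)
    a <- cx$atoms
    d2 <- (a$x - site$cbx)^2 + (a$y - site$cby)^2 + (a$z - site$cbz)^2
    own <- a$chain == site$chain & a$resno == site$resno
    side <- a$side[which(own)[1]]
    expect_setequal(reg$a,
                    which(own & !a$name %in% c("N", "CA", "C", "O", "CB")))
    expect_setequal(reg$b, which(d2 <= 100 & a$side == side & !own))
    expect_setequal(reg$c, which(d2 <= 100 & a$side != side))
    expect_length(intersect(reg$a, reg$b), 0)
  }
})

test_that("regions behave at the shell limits", {
  far <- read_complex(fix_toy(planted1 = integer(0), separation = 50)$pdb,
                      "A", "B")
  site <- make_site(far, "A", 3)
  reg <- partition_regions(far, site, 10)
  expect_length(reg$c, 0)
  # infinite shell: a + b + own backbone covers the whole same side
  reg_inf <- partition_regions(far, site, 1e9)
  own_bb <- which(far$atoms$chain == "A" & far$atoms$resno == "3" &
                    far$atoms$name %in% c("N", "CA", "C", "O", "CB"))
  expect_setequal(c(reg_inf$a, reg_inf$b, own_bb),
                  which(far$atoms$side == 1L))
  # monotonicity: larger shell never shrinks b or c
  cx <- fix_complex()
  site <- make_site(cx, "A", 3)
  prev_b <- prev_c <- integer(0)
  for (r in c(4, 6, 8, 10, 14)) {
    reg <- partition_regions(cx, site, r)
    expect_true(all(prev_b %in% reg$b))
    expect_true(all(prev_c %in% reg$c))
    prev_b <- reg$b; prev_c <- reg$c
  }
})

test_that("energy_vector matches the monolithic membership oracle", {
  cx <- fix_complex()
  sites <- find_interface_residues(cx)
  for (i in seq_len(nrow(sites))) {
    ev <- energy_vector(cx, sites[i, ], 10)
    expect_equal(ev, oracle_energy_vector(cx, sites[i, ], 10),
                 tolerance = 1e-11)
  }
})

test_that("energy_vector is zero-padded and rigid-body invariant", {
  far <- read_complex(fix_toy(planted1 = integer(0), separation = 50)$pdb,
                      "A", "B")
  ev <- energy_vector(far, make_site(far, "A", 3), 10)
  expect_true(all(ev[grep("inter", names(ev))] == 0))

  cx <- fix_complex()
  site <- make_site(cx, "A", 3)
  ev0 <- energy_vector(cx, site, 10)
  for (seed in 1:5) {
    cxt <- rigid_transform(cx, seed)
    cb <- cxt$atoms[cxt$atoms$chain == "A" & cxt$atoms$resno == "3" &
                      cxt$atoms$name == "CB", ]
    sitet <- list(chain = "A", resno = "3", cbx = cb$x, cby = cb$y,
                  cbz = cb$z)
    expect_equal(energy_vector(cxt, sitet, 10), ev0, tolerance = 1e-6)
  }
})
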