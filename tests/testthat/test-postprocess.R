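test_that("strain recovery is exact for rigid and linear displacement fields", {
  lm <- blob_labels(seed = 9L)
  mesh <- voxels_to_hexmesh(lm)
  # rigid translation -> zero strain
  u0 <- matrix(rep(c(0.3, -0.2, 0.7), each = nrow(mesh$nodes)), ncol = 3)
  expect_lt(max(abs(element_strain(mesh, u0)$values)), 1e-12)
  # uniaxial stretch u_x = alpha x
  alpha <- 2.5e-4
  ux <- cbind(alpha * mesh$nodes[, 1], 0, 0)
  st <- element_strain(mesh, ux)
  expect_equal(unname(st$values[, 1]), rep(alpha, nrow(mesh$elems)),
               tolerance = 1e-12)
  expect_lt(max(abs(st$values[, 2:6])), 1e-15)
  # small rotation -> strain below 1e-10
  theta <- c(1e-6, -2e-6, 1.5e-6)
  ur <- t(apply(mesh$nodes, 1, function(x) {
    c(theta[2] * x[3] - theta[3] * x[2],
      theta[3] * x[1] - theta[1] * x[3],
      theta[1] * x[2] - theta[2] * x[1])
  }))
  expect_lt(max(abs(element_strain(mesh, ur)$values)), 1e-10)
})

test_that("Hooke's law maps pure shear and uniaxial strain correctly", {
  E <- 14400; nu <- 0.309
  mesh <- assign_materials(voxels_to_hexmesh(label_map(array(1L, c(1, 1, 1)),
                                                       0.3)),
                           table = list(`1` = c(E = E, nu = nu)))
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  gam <- 3e-4
  shear <- perifem:::tensor_field(matrix(c(0, 0, 0, gam / 2, 0, 0), 1), "strain")
  sig <- element_stress(shear, mesh)$values
  expect_equal(sig[1, 4], mu * gam, tolerance = 1e-12)
  expect_lt(max(abs(sig[1, c(1:3, 5:6)])), 1e-15)
  e0 <- 1e-3
  uni <- perifem:::tensor_field(matrix(c(e0, 0, 0, 0, 0, 0), 1), "strain")
  sigu <- element_stress(uni, mesh)$values
  expect_equal(sigu[1, 1], (lam + 2 * mu) * e0, tolerance = 1e-12)
  expect_equal(sigu[1, 2], lam * e0, tolerance = 1e-12)
  # zero strain -> zero stress
  z <- perifem:::tensor_field(matrix(0, 1, 6), "strain")
  expect_true(all(element_stress(z, mesh)$values == 0))
})

test_that("von Mises obeys closed forms and rotation invariance", {
  expect_equal(von_mises(c(7, 7, 7, 0, 0, 0)), 0)
  expect_equal(von_mises(c(-3.2, 0, 0, 0, 0, 0)), 3.2)
  gam <- 0.4
  expect_equal(von_mises(c(0, 0, 0, gam, 0, 0)), sqrt(3) * gam)
  set.seed(13)
  for (i in 1:1000) {
    t6 <- rand_tensor6()
    R <- rand_rotation()
    vm1 <- von_mises(t6)
    vm2 <- von_mises(rotate_tensor6(t6, R))
    expect_lt(abs(vm1 - vm2) / max(vm1, 1e-12), 1e-10)
  }
})

test_that("principal values match the characteristic-cubic oracle", {
  expect_equal(unname(principal_values(c(3, 1, -2, 0, 0, 0))[1, ]),
               c(3, 1, -2))
  expect_equal(unname(principal_values(c(5, 5, 5, 0, 0, 0))[1, ]), c(5, 5, 5))
  set.seed(17)
  for (i in 1:1000) {
    t6 <- rand_tensor6()
    got <- principal_values(t6)[1, ]
    expect_equal(unname(got), eig_cubic_oracle(t6), tolerance = 1e-9)
  }
})

test_that("principal values are rotation invariant as a set", {
  set.seed(19)
  for (i in 1:200) {
    t6 <- rand_tensor6()
    R <- rand_rotation()
    expect_equal(unname(principal_values(t6)[1, ]),
                 unname(principal_values(rotate_tensor6(t6, R))[1, ]),
                 tolerance = 1e-9)
  }
})

test_that("equivalent strain obeys closed forms and links to von Mises", {
  expect_equal(equivalent_strain(c(0.01, 0.01, 0.01, 0, 0, 0)), 0)
  gam <- 6e-4
  expect_equal(equivalent_strain(c(0, 0, 0, gam / 2, 0, 0)), gam / sqrt(3),
               tolerance = 1e-15)
  # for isotropic elasticity, von_mises(sigma) = 3 mu equivalent_strain(eps)
  E <- 14400; nu <- 0.309; mu <- E / (2 * (1 + nu))
  mesh <- assign_materials(voxels_to_hexmesh(label_map(array(1L, c(1, 1, 1)),
                                                       0.3)),
                           table = list(`1` = c(E = E, nu = nu)))
  set.seed(23)
  for (i in 1:50) {
    e6 <- rand_tensor6() * 1e-3
    strain <- perifem:::tensor_field(matrix(e6, 1), "strain")
    sig <- element_stress(strain, mesh)
    expect_equal(von_mises(sig), 3 * mu * equivalent_strain(strain),
                 tolerance = 1e-9)
  }
})

test_that("interface summary reproduces a hand-computed 5-element fixture", {
  lab <- array(1L, c(7, 1, 1)); lab[4] <- 3L
  mesh <- assign_materials(voxels_to_hexmesh(label_map(lab, 0.3)),
                           variant = "refined")
  interface <- find_interface(mesh)
  expect_equal(length(interface), 2L)
  # fabricate per-element tensors (6 elements after meshing)
  ne <- nrow(mesh$elems)
  sig <- matrix(0, ne, 6); eps <- matrix(0, ne, 6)
  sig[interface[1], ] <- c(10, 0, 0, 0, 0, 0)     # uniaxial tension
  sig[interface[2], ] <- c(-4, -4, -4, 0, 0, 0)   # hydrostatic compression
  eps[interface[1], ] <- c(1e-3, 0, 0, 0, 0, 0)
  eps[interface[2], ] <- c(0, 0, 0, 5e-4, 0, 0)   # pure shear
  s <- summarize_interface(perifem:::tensor_field(sig, "stress"),
                           perifem:::tensor_field(eps, "strain"),
                           mesh, interface, variant = "refined")
  get <- function(m, col) s[[col]][s$measure == m]
  expect_equal(get("equivalent_stress", "max"), 10)
  expect_equal(get("equivalent_stress", "mean"), 5)      # (10 + 0) / 2
  expect_equal(get("tensile_stress", "max"), 10)
  expect_equal(get("tensile_stress", "mean"), 5)         # hydrostatic clamps to 0
  expect_equal(get("compressive_stress", "max"), 4)
  expect_equal(get("compressive_stress", "mean"), 2)
  expect_equal(get("equivalent_strain", "max"),
               max(2e-3 / 3, 1e-3 / sqrt(3)))
  expect_equal(get("tensile_strain", "max"), 1e-3)
  expect_equal(get("compressive_strain", "max"), 5e-4)
  expect_true(all(s$max >= s$mean))
  expect_error(summarize_interface(perifem:::tensor_field(sig, "stress"),
                                   perifem:::tensor_field(eps, "strain"),
                                   mesh, integer(0)), "empty")
})

test_that("model comparison computes percent changes and guards zero division", {
  lab <- array(1L, c(3, 1, 1)); lab[2] <- 3L
  mesh <- assign_materials(voxels_to_hexmesh(label_map(lab, 0.3)),
                           variant = "refined")
  interface <- find_interface(mesh)
  ne <- nrow(mesh$elems)
  sig <- matrix(1e-3 + seq_len(6 * ne), ne, 6); eps <- sig * 1e-5
  sf <- perifem:::tensor_field(sig, "stress")
  ef <- perifem:::tensor_field(eps, "strain")
  s1 <- summarize_interface(sf, ef, mesh, interface, "refined")
  cmp0 <- compare_models(s1, s1)
  expect_true(all(abs(cmp0$pct_change) < 1e-12))
  s2 <- s1; s2$max <- 2 * s2$max; s2$mean <- 2 * s2$mean
  cmp2 <- compare_models(s2, s1)
  expect_true(all(abs(cmp2$pct_change - 100) < 1e-9))
  expect_equal(nrow(cmp2), 12L)  # 6 measures x {max, mean}
  # zero simplified values are flagged, not NaN
  s3 <- s1; s3$max[1] <- 0; s3$mean[1] <- 0
  cmp3 <- compare_models(s1, s3)
  expect_true(all(!cmp3$defined[cmp3$measure == "equivalent_stress"]))
  expect_true(all(is.na(cmp3$pct_change[!cmp3$defined])))
  expect_true(all(is.finite(cmp3$pct_change[cmp3$defined])))
})

test_that("doubling the load doubles every interface measure", {
  tr <- generate_trabecular_specimen(tiny_spec(seed = 3L))
  mesh <- assign_materials(voxels_to_hexmesh(tr), variant = "refined")
  run_at <- function(load) {
    bcs <- build_bcs(mesh, load_N = load)
    sol <- assemble_and_solve(mesh, bcs, method = "direct")
    strain <- element_strain(mesh, sol)
    stress <- element_stress(strain, mesh)
    summarize_interface(stress, strain, mesh, find_interface(mesh))
  }
  s1 <- run_at(50); s2 <- run_at(100)
  expect_equal(s2$max, 2 * s1$max, tolerance = 1e-9)
  expect_equal(s2$mean, 2 * s1$mean, tolerance = 1e-9)
})

test_that("tidy and glance methods return well-formed tibbles", {
  lab <- array(1L, c(3, 1, 1)); lab[2] <- 3L
  mesh <- assign_materials(voxels_to_hexmesh(label_map(lab, 0.3)),
                           variant = "refined")
  ne <- nrow(mesh$elems)
  sf <- perifem:::tensor_field(matrix(rnorm(6 * ne), ne, 6), "stress")
  ef <- perifem:::tensor_field(matrix(rnorm(6 * ne) * 1e-4, ne, 6), "strain")
  s <- summarize_interface(sf, ef, mesh, find_interface(mesh), "refined")
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(nrow(glance(s)), 1L)
  cmp <- compare_models(s, s)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_true(is.finite(glance(cmp)$mean_stress_pct_change))
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})

test_that("VTK export round-trips through an independent parse", {
  tr <- generate_trabecular_specimen(tiny_spec(seed = 1L))
  mesh <- assign_materials(voxels_to_hexmesh(tr), variant = "refined")
  bcs <- build_bcs(mesh, load_N = 50)
  sol <- assemble_and_solve(mesh, bcs, tol = 1e-8)
  strain <- element_strain(mesh, sol)
  stress <- element_stress(strain, mesh)
  interface <- find_interface(mesh)
  f <- tempfile(fileext = ".vtk")
  export_fields(mesh, f, stress = stress, strain = strain, solution = sol,
                interface = interface)
  back <- read_vtk_legacy(f)
  expect_equal(nrow(back$cells), nrow(mesh$elems))
  expect_equal(nrow(back$points), nrow(mesh$nodes))
  expect_equal(sum(back$cell_data$interface_flag), length(interface))
  expect_equal(sum(back$cell_data$equivalent_stress),
               sum(von_mises(stress)), tolerance = 1e-9)
  expect_equal(back$point_data$displacement_mm, unname(sol$u),
               tolerance = 1e-12)
  # independent structural parse: header tokens and counts line up
  ln <- readLines(f)
  expect_identical(ln[4], "DATASET UNSTRUCTURED_GRID")
  ctypes <- grep("^CELL_TYPES", ln)
  expect_true(all(ln[(ctypes + 1):(ctypes + nrow(mesh$elems))] == "12"))
})
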