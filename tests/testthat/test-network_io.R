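test_that("incidence matrices round-trip and binarize on read", {
  set.seed(1)
  M <- random_incidence(3, 3)
  net <- bipartite_network(M)
  f <- withr::local_tempfile(fileext = ".csv")
  write_incidence_matrix(net, f)
  back <- read_incidence_matrix(f)
  expect_identical(back$incidence, net$incidence)

  # weighted counts are truncated to presence/absence
  tab <- rbind(c(0, 2), c(5, 0))
  dimnames(tab) <- list(c("p1", "p2"), c("a1", "a2"))
  write.table(data.frame(x = rownames(tab), tab, check.names = FALSE),
              f, sep = ",", row.names = FALSE, quote = FALSE)
  net2 <- read_incidence_matrix(f)
  expect_identical(as.vector(net2$incidence), c(0, 1, 1, 0))
  # idempotent: re-reading the binary output changes nothing
  write_incidence_matrix(net2, f)
  expect_identical(read_incidence_matrix(f)$incidence, net2$incidence)
})

test_that("degenerate rows and invalid entries are handled on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",a1,a2", "p1,1,1", "p2,0,0", "p3,1,0"), f)
  expect_warning(net <- read_incidence_matrix(f), "all-zero")
  expect_equal(nrow(net$incidence), 2)
  expect_identical(net$plant_labels, c("p1", "p3"))

  writeLines(c(",a1,a2", "p1,1,-1"), f)
  expect_error(read_incidence_matrix(f), "egative")
  writeLines(c(",a1,a2", "p1,0,0", "p2,0,0"), f)
  expect_error(suppressWarnings(read_incidence_matrix(f)), "all-zero")
})

test_that("edge lists build directed networks with mutual edges", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target", "A,B", "C,D", "A,B"), f)
  net <- read_edge_list(f)
  expect_equal(sum(net$adjacency), 2)  # duplicate collapsed
  expect_equal(net$adjacency["A", "B"], 1)
  expect_equal(net$adjacency["C", "D"], 1)

  writeLines(c("A,B", "B,A"), f)
  net2 <- read_edge_list(f)
  expect_equal(net2$adjacency["A", "B"] + net2$adjacency["B", "A"], 2)

  writeLines(c("A,A"), f)
  expect_error(read_edge_list(f), "elf-edge")
  writeLines(character(0), f)
  expect_error(read_edge_list(f))
})

test_that("food webs convert to resource-consumer bipartite form", {
  A <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  A["A", "B"] <- 1; A["B", "C"] <- 1
  bp <- foodweb_to_bipartite(directed_network(A))
  expect_identical(bp$plant_labels, c("A", "B"))
  expect_identical(bp$animal_labels, c("B", "C"))
  expect_equal(unname(bp$incidence), rbind(c(1, 0), c(0, 1)))

  Am <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  Am["A", "B"] <- 1; Am["B", "A"] <- 1
  bpm <- foodweb_to_bipartite(directed_network(Am))
  expect_equal(unname(bpm$incidence), rbind(c(0, 1), c(1, 0)))
})

test_that("bipartite conversion conserves links and degrees", {
  set.seed(42)
  for (rep in 1:10) {
    A <- random_adjacency(6)
    net <- directed_network(A)
    bp <- foodweb_to_bipartite(net)
    expect_equal(sum(bp$incidence), sum(A))
    out_deg <- rowSums(A)[rowSums(A) >= 1]
    expect_equal(unname(rowSums(bp$incidence)), unname(out_deg))
  }
})

test_that("site tables round-trip and reject invalid rows", {
  sim <- gen_site_table(20, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_table(sim$sites[1:5, ], f)
  back <- read_site_table(f)
  for (cc in c("latitude", "T_mean", "human_impact", "Z_NODF"))
    expect_equal(back[[cc]], sim$sites[[cc]][1:5], tolerance = 1e-10)
  expect_identical(back$network_id, sim$sites$network_id[1:5])

  bad <- sim$sites[1:5, ]
  bad$human_impact[3] <- 137
  write_site_table(bad, f)
  expect_error(read_site_table(f), "row 3.*human_impact")
})

test_that("bipartite-style species columns are derived and aliases accepted", {
  sim <- gen_site_table(20, seed = 4)
  df <- sim$sites[1:4, ]
  df$n_plants <- c(3, 4, 5, 6)
  df$n_animals <- c(7, 6, 5, 4)
  df$n_species <- NULL
  names(df)[names(df) == "latitude"] <- "Latitude"
  names(df)[names(df) == "n_links"] <- "#Links"
  f <- withr::local_tempfile(fileext = ".csv")
  write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE)
  back <- read_site_table(f)
  expect_equal(back$n_species, c(10, 10, 10, 10))

  df$`#Links` <- NULL
  write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_site_table(f), "n_links")
})

test_that("printed dataset-overlap and binary-fraction arithmetic", {
  expect_equal(jaccard_index(1:3, 2:4), 0.5)
  expect_equal(binary_fraction(1, 2), 50)
  expect_error(binary_fraction(3, 2))
})
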