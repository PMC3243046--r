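# Shared fixtures and independent oracles used across the test files.

# random admissible parameter draw for a family (assumes caller set a seed)
rand_admissible_spec <- function(family) {
  switch(family,
    linlog = transform_spec("linlog", theta = runif(1, 0.5, 50)),
    arcsinh = transform_spec("arcsinh", a = runif(1, 0, 2),
                             b = runif(1, 0.05, 3), c = runif(1, 0, 2)),
    biexp = transform_spec("biexp", a = runif(1, 0.05, 1),
                           b = runif(1, 0.05, 2), c = runif(1, 0.05, 1),
                           d = runif(1, 0.05, 2), f = 0,
                           w = runif(1, -2, 2)),
    boxcox = transform_spec("boxcox", theta = runif(1, 0.1, 3)),
    log = transform_spec("log"),
    identity = transform_spec("identity"))
}

# admissible raw-scale grid for roundtrip checks per family; the signed
# Box-Cox is only globally invertible on y > 0, and log needs y > 0
roundtrip_grid <- function(family, theta = NULL) {
  full <- seq(-100, 10000, length.out = 401)
  switch(family,
    boxcox = seq(1e-3, 10000, length.out = 401),
    log = seq(1e-3, 10000, length.out = 401),
    linlog = full,
    full)
}

# brute-force optimal label matching (all permutations), K <= 5
brute_force_misclassification <- function(true_labels, predicted_labels) {
  lt <- sort(unique(true_labels))
  lp <- sort(unique(predicted_labels))
  m <- max(length(lt), length(lp))
  stopifnot(m <= 5)
  conf <- matrix(0, m, m)
  for (i in seq_along(true_labels)) {
    conf[match(predicted_labels[i], lp), match(true_labels[i], lt)] <-
      conf[match(predicted_labels[i], lp), match(true_labels[i], lt)] + 1
  }
  perms <- all_permutations(m)
  agree <- apply(perms, 1, function(pp) sum(conf[cbind(seq_len(m), pp)]))
  1 - max(agree) / length(true_labels)
}

all_permutations <- function(m) {
  if (m == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(m - 1)
  do.call(rbind, lapply(seq_len(m), function(k) {
    rest <- setdiff(seq_len(m), k)
    cbind(k, matrix(rest[sub], nrow(sub), m - 1))
  }))
}

# random SPD matrix
rand_spd <- function(d) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) + diag(0.5, d)
}

rand_population <- function(sample_id, pop_index, d = 2) {
  population(sample_id = sample_id, pop_index = pop_index,
             mu = rnorm(d, sd = 3), sigma = rand_spd(d), nu = 4,
             size = sample(20:200, 1))
}

# minimal FCS 3.0 writer (float32, little-endian, list mode) so the FCS
# reader can be tested without shipping binary fixtures
write_minimal_fcs <- function(mat, path) {
  npar <- ncol(mat); ntot <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(npar), "$TOT", as.character(ntot))
  for (j in seq_len(npar)) {
    kw <- c(kw, paste0("$P", j, "N"), colnames(mat)[j],
            paste0("$P", j, "B"), "32",
            paste0("$P", j, "E"), "0,0",
            paste0("$P", j, "R"), "262144")
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_beg <- 58L
  text_end <- text_beg + nchar(text) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * npar * ntot - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
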