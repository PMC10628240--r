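# Independent oracles: plain-loop reimplementations kept deliberately
# separate from the package's vectorized code paths.

# ---- numbering oracle: exhaustive placement search with explicit loops ----

.oracle_geo <- list(
  heavy = list(
    fr1 = "EVQLVESGGGLVQPGGSLRLSCAASGFTFS", fr2 = "WVRQAPGKGLEWVS",
    fr3 = "RVTISRDNSKNTLYLQMNSLRAEDTAVYY", fr4 = "WGQGTLVTVSS",
    i_site3 = 17, tr = 0:5, c1r = 1:7, c2r = 14:19, kr = 0:3,
    c3r = 3:19, n4r = 0:11
  ),
  light = list(
    fr1 = "DIQMTQSPSSLSASVGDRVTITC", fr2 = "WYQQKPGKAPKLLIY",
    fr3 = "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", fr4 = "FGQGTKVEIK",
    i_site3 = 32, tr = 0:5, c1r = 8:17, c2r = 7, kr = 0,
    c3r = 3:15, n4r = 0:10
  )
)

# number of matching characters between s[from..] and a template string
.oracle_matches <- function(chars, from, tmpl_chars) {
  m <- 0L
  for (i in seq_along(tmpl_chars)) {
    if (chars[from + i - 1L] == tmpl_chars[i]) m <- m + 1L
  }
  m
}

oracle_segment <- function(sequence, chain_type) {
  g <- .oracle_geo[[chain_type]]
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  f1 <- strsplit(g$fr1, "")[[1]]; f2 <- strsplit(g$fr2, "")[[1]]
  f3 <- strsplit(g$fr3, "")[[1]]; f4 <- strsplit(g$fr4, "")[[1]]
  # light chain CDR2 is fixed length 7
  cand <- list()
  for (t in g$tr) for (c1 in g$c1r) for (c2 in g$c2r) for (k in g$kr) {
    n1 <- length(f1) - t
    for (n4 in g$n4r) {
      c3 <- L - n1 - c1 - length(f2) - c2 - (length(f3) + k) - n4
      if (!(c3 %in% g$c3r)) next
      o2 <- n1 + c1 + 1L
      o3 <- o2 + length(f2) + c2
      m <- .oracle_matches(chars, 1L, f1[(t + 1L):length(f1)]) +
        .oracle_matches(chars, o2, f2)
      if (g$i_site3 < length(f3)) {
        m <- m + .oracle_matches(chars, o3, f3[1:g$i_site3]) +
          .oracle_matches(chars, o3 + g$i_site3 + k,
                          f3[(g$i_site3 + 1L):length(f3)])
      } else {
        m <- m + .oracle_matches(chars, o3, f3)
      }
      if (n4 > 0) m <- m + .oracle_matches(chars, L - n4 + 1L, f4[1:n4])
      cand[[length(cand) + 1L]] <- data.frame(
        t = t, c1 = c1, c2 = c2, k = k, c3 = c3, n4 = n4, matches = m,
        compared = n1 + length(f2) + length(f3) + n4,
        identity = m / (n1 + length(f2) + length(f3) + n4)
      )
    }
  }
  cand <- do.call(rbind, cand)
  tc1 <- if (chain_type == "heavy") 5 else 11
  tc2 <- if (chain_type == "heavy") 16 else 7
  tc3 <- if (chain_type == "heavy") 8 else 9
  ord <- order(-cand$matches, -cand$compared, cand$k, cand$t,
               abs(cand$c1 - tc1), cand$c1, abs(cand$c2 - tc2), cand$c2,
               abs(cand$c3 - tc3), cand$c3)
  cand[ord[1], ]
}

# ---- independent fixed-column PDB parser ----

oracle_read_pdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  data.frame(
    elety = trimws(substr(lines, 13, 16)),
    resid = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resno = as.integer(substr(lines, 23, 26)),
    ins = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    altloc = trimws(substr(lines, 17, 17)),
    stringsAsFactors = FALSE
  )
}

# minimum heavy-atom distance for every residue pair across two residue
# sets, by brute-force double loop
oracle_pair_min_dists <- function(atoms, keys_a, keys_b) {
  atoms$key <- paste0(atoms$chain, "/", atoms$resno, atoms$ins)
  out <- list()
  for (ka in unique(keys_a)) {
    a <- atoms[atoms$key == ka, ]
    for (kb in unique(keys_b)) {
      b <- atoms[atoms$key == kb, ]
      dmin <- Inf
      for (i in seq_len(nrow(a))) {
        d <- sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2 + (a$z[i] - b$z)^2)
        dmin <- min(dmin, d)
      }
      out[[length(out) + 1L]] <- data.frame(res_a = ka, res_b = kb,
                                            min_distance = dmin)
    }
  }
  do.call(rbind, out)
}

# ---- rigid-body motion ----

rotation_matrix <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3,
               byrow = TRUE)
  rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

transform_model <- function(model, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rot)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

# toy single-residue atom table for classification tests
toy_atoms <- function(elety, element, xyz) {
  tibble::tibble(elety = elety, element = element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
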