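# Shared fixtures and independent oracles.

# A pure-CT toy morphometry table (no cast subtrees): leaves stay terminal.
ct_only_table <- function(ct) {
  cast <- data.frame(order = 1L, len_mean = 1, len_sd = 0,
                     rad_mean = 0.6, rad_sd = 0, delta_n = 1L)
  morphometry_table(ct, cast, terminal_order = 1L)
}

# Balanced binary CT tree with `gens` generations below the root
# (gens = 0 is a single segment).  Radii/lengths vary per segment so the
# ladder oracle is exercised on asymmetric numbers.
balanced_ct <- function(gens, r0 = 0.9, l0 = 6) {
  ids <- "s1"; parents <- NA_character_
  radius <- r0; length_mm <- l0
  prev <- "s1"; counter <- 1L
  for (g in seq_len(gens)) {
    nxt <- character(0)
    for (p in prev) {
      for (k in 1:2) {
        counter <- counter + 1L
        id <- paste0("s", counter)
        ids <- c(ids, id); parents <- c(parents, p)
        radius <- c(radius, r0 * 0.87^g * (1 + 0.1 * (k - 1.5)))
        length_mm <- c(length_mm, l0 * 0.75^g * (1 + 0.2 * (k - 1.5)))
        nxt <- c(nxt, id)
      }
    }
    prev <- nxt
  }
  ct_only_table(data.frame(id = ids, parent = parents,
                           length_mm = length_mm, radius_mm = radius,
                           stringsAsFactors = FALSE))
}

# Independent top-down ladder-network oracle: explicit series/parallel
# combination by complex division, recursing from the root.  Terminal
# impedances are a matrix (one row per terminal, in tree order).
ladder_impedance <- function(tree, Zterm, const, grid,
                             gas_shunt = TRUE, wall_shunt = TRUE) {
  seg <- tree$segments
  w <- attr(grid, "omega")
  children <- lapply(seq_len(nrow(seg)), function(i) which(seg$parent == i))
  trow <- integer(nrow(seg)); trow[seg$terminal] <- seq_len(sum(seg$terminal))
  comp <- segment_impedance(seg$radius, seg$length, const)
  eval_node <- function(i) {
    if (seg$terminal[i]) {
      Zdown <- Zterm[trow[i], ]
    } else {
      kids <- lapply(children[[i]], eval_node)
      Y <- Reduce(`+`, lapply(kids, function(z) ifelse(is.finite(Re(z)), 1 / z, 0)))
      Zdown <- ifelse(Mod(Y) > 0, 1 / Y, complex(real = Inf, imaginary = Inf))
    }
    out <- Zdown
    openf <- is.finite(Re(Zdown))
    if (any(openf)) {
      Zl2 <- (comp$R_seg[i] + 1i * w * comp$I_seg[i]) / 2
      Zmid <- Zdown[openf] + Zl2[openf]
      Ysh <- 0
      if (gas_shunt) Ysh <- Ysh + 1i * w[openf] * comp$C_g[i]
      if (wall_shunt) Ysh <- Ysh +
        w[openf]^comp$alpha_w[i] / complex(real = comp$G_w[i], imaginary = -comp$H_w[i])
      out[openf] <- 1 / (1 / Zmid + Ysh) + Zl2[openf]
    }
    out
  }
  root <- which(is.na(seg$parent))
  eval_node(root)
}

# Brute-force enumeration of the dichotomous cast recursion: number of
# terminals below a branch of a given order.
enumerate_terminals <- function(order, delta_by_order, terminal_order, min_order) {
  if (order <= terminal_order) return(1L)
  d <- delta_by_order[[as.character(order)]]
  kids <- pmax(c(order - 1L, order - 1L - d), min_order)
  sum(vapply(kids, enumerate_terminals, 0L,
             delta_by_order = delta_by_order,
             terminal_order = terminal_order, min_order = min_order))
}

# Random constant-phase terminal spectra for oracle tests.
random_cp_terminals <- function(n_terminal, grid, seed) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    t(sapply(seq_len(n_terminal), function(i) {
      p <- constant_phase_params(stats::runif(1, 0.01, 0.3),
                                 stats::runif(1, 1e-4, 1e-2),
                                 stats::runif(1, 2, 10) * 1000,
                                 stats::runif(1, 20, 80) * 1000)
      constant_phase_impedance(p, grid)$Z
    }))
  })
}
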