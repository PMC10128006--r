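# Brute-force grid-search oracle for small non-negative least-squares
# problems: enumerates extent vectors on a regular grid and returns the
# minimal weighted residual sum of squares (and its argmin). Independent of
# the active-set solver used by fit_extents; only feasible for <= 3 reactions.
grid_nnls <- function(S, y, w, upper, step = 0.001) {
  sw <- sqrt(w)
  Sw <- S * sw
  yw <- as.vector(y * sw)
  G <- crossprod(Sw)
  h <- as.vector(crossprod(Sw, yw))
  c0 <- sum(yw^2)
  k <- ncol(S)
  stopifnot(k >= 1, k <= 3, length(upper) == k)
  g <- lapply(seq_len(k), function(j) seq(0, upper[j], by = step))
  if (k == 1L) {
    obj <- c0 - 2 * g[[1]] * h[1] + g[[1]]^2 * G[1, 1]
    i <- which.min(obj)
    return(list(objective = obj[i], argmin = g[[1]][i]))
  }
  q1 <- g[[1]]^2 * G[1, 1] - 2 * g[[1]] * h[1]
  q2 <- g[[2]]^2 * G[2, 2] - 2 * g[[2]] * h[2]
  base12 <- outer(q1, q2, "+") + 2 * G[1, 2] * outer(g[[1]], g[[2]])
  if (k == 2L) {
    i <- arrayInd(which.min(base12), dim(base12))
    return(list(objective = base12[i] + c0,
                argmin = c(g[[1]][i[1]], g[[2]][i[2]])))
  }
  best <- Inf
  arg <- NULL
  for (x3 in g[[3]]) {
    M <- base12 +
      outer(2 * x3 * G[1, 3] * g[[1]], 2 * x3 * G[2, 3] * g[[2]], "+") +
      (x3^2 * G[3, 3] - 2 * x3 * h[3])
    m <- min(M)
    if (m < best) {
      best <- m
      i <- arrayInd(which.min(M), dim(M))
      arg <- c(g[[1]][i[1]], g[[2]][i[2]], x3)
    }
  }
  list(objective = best + c0, argmin = arg)
}

# weighted residual sum of squares of a fit (comparable to grid_nnls)
fit_rss <- function(fit) fit$residual_norm^2

# two-reaction fermenter-only model (lactate fermentation + acetogenesis)
toy2_model <- function() assemble_model("Rc", sulfate_present = FALSE)

# three reactions: the fermenter routes plus hydrogenotrophic methanogenesis
toy3_model <- function() assemble_model(c("Rc", "Mh"), sulfate_present = FALSE)

# model with two stoichiometrically identical reactions (duplicated columns):
# individual extents are unidentifiable, only their sum is constrained
duplicated_model <- function() {
  rx <- c(glucose = -1, acetate = 2, co2 = 2, h2 = 4)
  assemble_model("Rc", FALSE, reactions = list(
    copy_a = reaction("copy_a", "Rc", rx),
    copy_b = reaction("copy_b", "Rc", rx)))
}

# carbon / electron totals of a net-change style vector
elemental_totals <- function(v) {
  mets <- metabolite_table()
  idx <- match(names(v), mets$id)
  c(carbon = sum(v * mets$carbon_atoms[idx]),
    electrons = sum(v * mets$electron_equivalents[idx]))
}

table1_obs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_observations(synflux_table1())
    cache
  }
})

quad_fit <- function(condition = c("control", "sulfate")) {
  condition <- match.arg(condition)
  m <- assemble_model(c("Rc", "Mh", "Mc", "Dv"), condition == "sulfate")
  o <- table1_obs()[[if (condition == "control") "quad" else "quad_S"]]
  y <- net_change_vector(o, m)
  list(model = m, y = y, fit = fit_extents(m, y))
}
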