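# small internal helpers shared across modules

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

norm_vec <- function(v) v / sqrt(sum(v^2))

rand_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  th <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(th), r * sin(th), z)
}

# micrometre <-> centimetre unit bridge, kept in one audited place
UM_PER_CM <- 1e4
um_to_cm <- function(x_um) x_um / UM_PER_CM
cm_to_um <- function(x_cm) x_cm * UM_PER_CM

# concentric (Shirley-Chiu) mapping of the unit square onto the unit disk;
# u, v in [0,1), vectorized
concentric_disk <- function(u, v) {
  ox <- 2 * u - 1
  oy <- 2 * v - 1
  r <- numeric(length(u)); th <- numeric(length(u))
  nz <- !(ox == 0 & oy == 0)
  big_x <- nz & abs(ox) > abs(oy)
  r[big_x] <- ox[big_x]
  th[big_x] <- (pi / 4) * (oy[big_x] / ox[big_x])
  big_y <- nz & !big_x
  r[big_y] <- oy[big_y]
  th[big_y] <- pi / 2 - (pi / 4) * (ox[big_y] / oy[big_y])
  cbind(r * cos(th), r * sin(th))
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits (provenance tag)
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0x811C9DC5
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)   # xor touches the low byte only
    # 32-bit multiply by the FNV prime 16777619 = 2^24 + 403, kept exact in
    # doubles: (h * 2^24) mod 2^32 == (h mod 2^8) * 2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%08x", h)
}
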