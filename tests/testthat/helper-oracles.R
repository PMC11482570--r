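# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: distances via the hypotenuse formula,
# angles via normalised-vector atan2, signed angles via cross/dot
# products.

oracle_dist <- function(p, q) {
  unname(sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2))
}

# interior angle at vertex `at` between rays to p and q, degrees
oracle_angle <- function(at, p, q) {
  v1 <- p - at
  v2 <- q - at
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  dot <- sum(v1 * v2)
  unname(abs(atan2(cross, dot)) * 180 / pi)
}

# signed profile angle at A: interior angle if C ventral of the AB
# line, 360 - interior if dorsal (dorsal given by unit vector d)
oracle_profile <- function(A, B, C, d) {
  theta <- oracle_angle(A, B, C)
  ab <- B - A
  ab <- ab / sqrt(sum(ab^2))
  ac <- C - A
  perp <- ac - sum(ac * ab) * ab
  s <- sum(perp * d)
  if (abs(s) < 1e-12) 180 else if (s > 0) 360 - theta else theta
}

random_triple <- function() {
  repeat {
    pts <- matrix(runif(6, -50, 50), 3, 2)
    d <- c(oracle_dist(pts[1, ], pts[2, ]), oracle_dist(pts[1, ], pts[3, ]),
           oracle_dist(pts[2, ], pts[3, ]))
    if (min(d) > 1e-3) {
      return(landmark_triple(pts[1, ], pts[2, ], pts[3, ]))
    }
  }
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
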