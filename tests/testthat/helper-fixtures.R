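# Shared fixture builders.  Everything is generated in code; no binary data.

archaeal_anchors <- function() builtin_anchor_set("archaeal_chimera")

# Ring with distinct per-subunit twists and interface distances, so that no
# accidental symmetry hides indexing errors.
asymmetric_ring <- function(seed = 1L) {
  make_ring(ring_spec(
    per_subunit_twist = c(-10, -20, -30, 5, 15, 25),
    interface_atp = c(5.0, 6.0, 7.0, 5.5, 6.5, 7.5),
    interface_h2i = c(7.0, 7.2, 7.4, 7.6, 7.8, 7.9),
    seed = seed))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
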