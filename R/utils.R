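# Parameter transforms between constrained and unconstrained scales,
# used by the MCMC sampler (random walks happen on the unconstrained
# scale; log-Jacobians keep the target correct).

# kind "lb_ub": x in (a, b) via scaled logit; "ub": x < b via b - exp(z);
# "id": unbounded.
.tr <- function(kind, a = NA_real_, b = NA_real_) {
  list(kind = kind, a = a, b = b)
}

.tr_to_x <- function(z, tr) {
  switch(tr$kind,
         lb_ub = tr$a + (tr$b - tr$a) * stats::plogis(z),
         ub = tr$b - exp(z),
         id = z)
}

.tr_to_z <- function(x, tr) {
  switch(tr$kind,
         lb_ub = stats::qlogis((x - tr$a) / (tr$b - tr$a)),
         ub = log(tr$b - x),
         id = x)
}

# log |dx/dz|
.tr_ljac <- function(z, tr) {
  switch(tr$kind,
         lb_ub = {
           p <- stats::plogis(z)
           log(tr$b - tr$a) + log(p) + log1p(-p)
         },
         ub = z,
         id = 0)
}
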