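# hand-written reference expansion of the FitzHugh-Nagumo model under the
# two-stage Heun (modified Euler) scheme: the 16 printed time-evolution
# equations, written with independent scalar names so the comparison with the
# generated program is a genuine alpha-equivalence check
golden_fhn_heun <- function() {
  v <- mx_var; n <- mx_num; o <- mx_op
  asn <- function(lhs, rhs) list(lhs = lhs, rhs = rhs)
  fx <- function(x, r, y) o("add", o("sub", o("sub", v(x), o("div", v(r), n("3.0"))), v(y)), v("A"))
  fy <- function(x, y) o("mul", v("B"), o("sub", o("add", v(x), v("C")), o("mul", v("D"), v(y))))
  upd <- function(x0, k) o("add", v(x0), o("mul", v(k), v("DEL")))
  comb <- function(x0, k1, k2) o("add", v(x0),
    o("mul", o("mul", n("0.5"), o("add", v(k1), v(k2))), v("DEL")))
  list(
    asn("X0", v("Xt")),
    asn("Y0", v("Yt")),
    asn("T0", v("Tcur")),
    asn("R0", o("pow", v("X0"), n("3"))),
    asn("K1X", fx("X0", "R0", "Y0")),
    asn("K1Y", fy("X0", "Y0")),
    asn("X1", upd("X0", "K1X")),
    asn("Y1", upd("Y0", "K1Y")),
    asn("T1", o("add", v("T0"), v("DEL"))),
    asn("R1", o("pow", v("X1"), n("3"))),
    asn("K2X", fx("X1", "R1", "Y1")),
    asn("K2Y", fy("X1", "Y1")),
    asn("X2", comb("X0", "K1X", "K2X")),
    asn("Y2", comb("Y0", "K1Y", "K2Y")),
    asn("Xnext", v("X2")),
    asn("Ynext", v("Y2"))
  )
}
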