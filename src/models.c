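/* Right-hand sides of the three gene-circuit models, compiled for use
 * with deSolve's compiled-model interface.  The stimulus enters as a
 * forcing function (linearly interpolated by the integrator); the LPS
 * model additionally receives delay-shifted copies of the stimulus as
 * extra forcings, so no dedicated DDE solver is required.
 *
 * Parameter vectors are passed from R in a fixed order; see the matching
 * constructors in R/models.R.
 */

#include <R.h>
#include <math.h>

static double hill_act(double x, double K, double n)
{
    if (x <= 0.0) return 0.0;
    double xn = pow(x, n), Kn = pow(K, n);
    return xn / (Kn + xn);
}

/* ---------------- GAL: dual positive/negative feedback ---------------- */

#define GAL_NPAR 16
static double gal_p[GAL_NPAR];
static double gal_u[1];

void gal_init(void (*odeparms)(int *, double *))
{
    int n = GAL_NPAR;
    odeparms(&n, gal_p);
}

void gal_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, gal_u);
}

/* p: b3 V3 d3 b80 V80 d80 bT VT dT Ku nu Kseq K80 n80 spos sneg
 * y: Gal3, Gal80, Target */
void gal_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double u = gal_u[0];
    if (u < 0.0) u = 0.0;
    double actu = hill_act(u, gal_p[9], gal_p[10]);
    double g3s = y[0] * actu;                       /* active Gal3 */
    double g80f = y[1] / (1.0 + g3s / gal_p[11]);   /* free Gal80 */
    double r = g80f / gal_p[12];
    double A = 1.0 / (1.0 + pow(r, gal_p[13]));     /* Gal4 activity */

    ydot[0] = gal_p[0] + gal_p[14] * gal_p[1] * A - gal_p[2] * y[0];
    ydot[1] = gal_p[3] + gal_p[15] * gal_p[4] * A - gal_p[5] * y[1];
    ydot[2] = gal_p[6] + gal_p[7] * A - gal_p[8] * y[2];
}

/* -------- OLE: positive FBL plus coherent type-1/type-2 FFLs ---------- */

#define OLE_NPAR 34
static double ole_p[OLE_NPAR];
static double ole_u[1];

void ole_init(void (*odeparms)(int *, double *))
{
    int n = OLE_NPAR;
    odeparms(&n, ole_p);
}

void ole_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, ole_u);
}

/* p: bA VA dA bO VO dO bP VP dP bT VT dT
 *    Ko no KuA nuA KuO nuO KA nA K3 n3 Kp np
 *    wP1 wP2 w1 w2 c0 spos sneg adr1_del oaf3_del no_pf
 * y: Adr1, Oaf3, Pip2, Target */
void ole_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double u = ole_u[0];
    if (u < 0.0) u = 0.0;
    double spos = ole_p[29], sneg = ole_p[30];
    int adr1_del = ole_p[31] > 0.5, oaf3_del = ole_p[32] > 0.5;
    int no_pf = ole_p[33] > 0.5;

    double O1 = hill_act(u, ole_p[12], ole_p[13]);  /* Oaf1 activity */
    double actA = adr1_del ? 0.0 : hill_act(y[0], ole_p[18], ole_p[19]);
    double rep3 = 1.0;
    if (!oaf3_del && y[1] > 0.0)
        rep3 = 1.0 / (1.0 + sneg * pow(y[1] / ole_p[20], ole_p[21]));
    double actP = hill_act(y[2], ole_p[22], ole_p[23]);
    double OP = O1 * actP;                          /* Oaf1-Pip2 dimer */
    /* PIP2 promoter input: autoregulatory (OP) unless the positive
     * feedback is severed, plus the Adr1 feed-forward arm */
    double pip2_self = no_pf ? ole_p[28] * O1 : OP;
    double pip2_in = ole_p[24] * pip2_self + spos * ole_p[25] * actA;
    /* Oaf3 competes at the Oaf1-Pip2-bound promoter element, so its
     * repression gates the heterodimer arm; the Adr1 arm is independent */
    double targ_in = ole_p[26] * OP * rep3 + spos * ole_p[27] * actA;

    ydot[0] = adr1_del ? -ole_p[2] * y[0]
        : ole_p[0] + ole_p[1] * hill_act(u, ole_p[14], ole_p[15])
          - ole_p[2] * y[0];
    ydot[1] = oaf3_del ? -ole_p[5] * y[1]
        : ole_p[3] + ole_p[4] * hill_act(u, ole_p[16], ole_p[17])
          - ole_p[5] * y[1];
    ydot[2] = ole_p[6] + ole_p[7] * pip2_in - ole_p[8] * y[2];
    ydot[3] = ole_p[9] + ole_p[10] * targ_in - ole_p[11] * y[3];
}

/* --------- LPS: delayed coherent type-1/type-2 feed-forward ----------- */

#define LPS_NPAR 17
static double lps_p[LPS_NPAR];
static double lps_u[3];                 /* u(t), u(t - tauA), u(t - tauC) */

void lps_init(void (*odeparms)(int *, double *))
{
    int n = LPS_NPAR;
    odeparms(&n, lps_p);
}

void lps_forc(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, lps_u);
}

/* p: bA VA dA bC VC dC bT VT dT Kn nn KC nC KA3 nA3 spos sneg
 * y: ATF3, CEBPd, Target */
void lps_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double u0 = lps_u[0] > 0.0 ? lps_u[0] : 0.0;
    double uA = lps_u[1] > 0.0 ? lps_u[1] : 0.0;
    double uC = lps_u[2] > 0.0 ? lps_u[2] : 0.0;
    double spos = lps_p[15], sneg = lps_p[16];

    double actC = hill_act(y[1], lps_p[11], lps_p[12]);
    double rep = 1.0;
    if (y[0] > 0.0)
        rep = 1.0 / (1.0 + sneg * pow(y[0] / lps_p[13], lps_p[14]));

    ydot[0] = lps_p[0] + spos * lps_p[1] * hill_act(uA, lps_p[9], lps_p[10])
        - lps_p[2] * y[0];
    ydot[1] = lps_p[3] + spos * lps_p[4] * hill_act(uC, lps_p[9], lps_p[10])
        - lps_p[5] * y[1];
    ydot[2] = lps_p[6]
        + lps_p[7] * spos * hill_act(u0, lps_p[9], lps_p[10]) * actC * rep
        - lps_p[8] * y[2];
}
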