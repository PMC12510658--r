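/* Mass-action right-hand sides for the phosphoinositide pathway model family.
 *
 * State order (shared by all variants):
 *   0 PI, 1 PI4P, 2 PIP2, 3 PIP3, 4 PI34P2, 5 Pp, 6 IP3, 7 IP1, 8 Ip,
 *   9 extension slot (PIc in A03, PIP3b in A04, PIP2b in A05).
 *
 * Parameter vector layout (see R/ppi-model.R, .ppi_pack_parms):
 *   0      variant index: 0 = A0, 1 = A01, ..., 10 = A10
 *   1..4   stimulus a1, a2, a3, a4
 *   5..10  r1, rm1, r2, rm2, r3, r4
 *   11..18 th1, th2, th3, thm3, th4, thm4, th5, thm5
 *   19..21 s1, s2, sm2
 *   22..29 th6, thm6, s4, sm4, s5, sm5, r6, thm2   (variant extras, 0 if unused)
 *
 * The system is closed: every flux appears once with +, once with -, so the
 * componentwise sum of the derivative is identically zero.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#undef PI   /* R_ext/Constants.h aliases PI to M_PI; PI is a state here */

#define N_PARMS 30

static double parms[N_PARMS];

void ppi_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static void ppi_rhs_core(const double *p, double t, const double *y,
                         double *dy, int neq)
{
    int v = (int)(p[0] + 0.5);
    double stim = p[1] * t * exp(-p[2] * t * t) + p[3] * tanh(p[4] * t);

    double PI = y[0], PI4P = y[1], PIP2 = y[2], PIP3 = y[3], PI34P2 = y[4];
    double Pp = y[5], IP3 = y[6], IP1 = y[7], Ip = y[8];
    double extra = (neq > 9) ? y[9] : 0.0;

    double r1 = p[5], rm1 = p[6], r2 = p[7], rm2 = p[8], r3 = p[9], r4 = p[10];
    double th1 = p[11], th2 = p[12], th3 = p[13], thm3 = p[14];
    double th4 = p[15], thm4 = p[16], th5 = p[17], thm5 = p[18];
    double s1 = p[19], s2 = p[20], sm2 = p[21];
    double th6 = p[22], thm6 = p[23], s4 = p[24], sm4 = p[25];
    double s5 = p[26], sm5 = p[27], r6 = p[28], thm2 = p[29];

    /* A0 fluxes; variants swap in a modifier-promoted form */
    double f_r1 = (v == 6) ? r1 * IP3 * PI : r1 * PI;          /* PI -> PI4P   */
    double f_rm1 = (v == 7) ? rm1 * PI4P * PI4P : rm1 * PI4P;  /* PI4P -> PI   */
    double f_r2 = (v == 2) ? r2 * IP3 * PI4P : r2 * PI4P;      /* PI4P -> PIP2 */
    double f_rm2 = rm2 * PIP2;                                 /* PIP2 -> PI4P */
    double f_s2 = s2 * stim * PIP2;                            /* PIP2 -> PIP3 */
    double f_sm2 = sm2 * PIP3;                                 /* PIP3 -> PIP2 */
    double f_s1 = s1 * stim * PIP2;                            /* PIP2 -> IP3  */
    double f_r4 = (v == 1) ? r4 * stim * PIP3 : r4 * PIP3;     /* PIP3 -> PI34P2 */
    double f_th3 = th3 * PI;                                   /* PI -> Pp     */
    double f_thm3 = thm3 * Pp;                                 /* Pp -> PI     */
    double f_th5 = th5 * Pp;                                   /* Pp -> PIP2   */
    double f_thm5 = thm5 * PIP2;                               /* PIP2 -> Pp   */
    double f_th4 = (v == 8) ? th4 * PIP2 * Pp : th4 * Pp;      /* Pp -> PI34P2 */
    double f_thm4 = thm4 * PI34P2;                             /* PI34P2 -> Pp */
    double f_th1 = th1 * IP3;                                  /* IP3 -> IP1   */
    double f_r3 = r3 * IP1;                                    /* IP1 -> Ip    */
    /* th2: Ip -> PI in all variants except A03 where it is PIc -> PI */
    double f_th2 = (v == 3) ? th2 * extra : th2 * Ip;

    double dPI = f_th2 - f_r1 + f_rm1 - f_th3 + f_thm3;
    double dPI4P = f_r1 - f_rm1 - f_r2 + f_rm2;
    double dPIP2 = f_r2 - f_rm2 - f_s2 + f_sm2 - f_s1 + f_th5 - f_thm5;
    double dPIP3 = f_s2 - f_sm2 - f_r4;
    double dPI34P2 = f_r4 + f_th4 - f_thm4;
    double dPp = f_th3 - f_thm3 - f_th5 + f_thm5 - f_th4 + f_thm4;
    double dIP3 = f_s1 - f_th1;
    double dIP1 = f_th1 - f_r3;
    double dIp = f_r3 - f_th2;
    double dextra = 0.0;

    if (v == 3) {            /* secondary PtdIns pool: Ip <-> PIc -> PI */
        double f_th6 = th6 * Ip, f_thm6 = thm6 * extra;
        dIp = f_r3 - f_th6 + f_thm6;   /* th2 now leaves PIc, not Ip */
        dextra = f_th6 - f_thm6 - f_th2;
    } else if (v == 4) {     /* stimulated PIP3 sequestration by PH domains */
        double f_s4 = s4 * stim * PIP3, f_sm4 = sm4 * extra;
        dPIP3 += -f_s4 + f_sm4;
        dextra = f_s4 - f_sm4;
    } else if (v == 5) {     /* MARCKS-bound PIP2, calcium-surrogate release */
        double f_s5 = s5 * PIP2, f_sm5 = sm5 * IP3 * extra;
        dPIP2 += -f_s5 + f_sm5;
        dextra = f_s5 - f_sm5;
    } else if (v == 9) {     /* direct PI4P -> PI34P2 synthesis */
        double f_r6 = r6 * PI4P;
        dPI4P -= f_r6;
        dPI34P2 += f_r6;
    } else if (v == 10) {    /* calcium-promoted PI -> Ip shunt */
        double f_thm2 = thm2 * IP3 * PI;
        dPI -= f_thm2;
        dIp += f_thm2;
    }

    dy[0] = dPI; dy[1] = dPI4P; dy[2] = dPIP2; dy[3] = dPIP3; dy[4] = dPI34P2;
    dy[5] = dPp; dy[6] = dIP3; dy[7] = dIP1; dy[8] = dIp;
    if (neq > 9) dy[9] = dextra;
}

/* deSolve entry point */
void ppi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    ppi_rhs_core(parms, *t, y, ydot, *neq);
}

/* direct evaluation from R, for testing and the exported rhs evaluator */
SEXP C_ppi_rhs(SEXP t, SEXP y, SEXP p)
{
    int neq = LENGTH(y);
    if (LENGTH(p) != N_PARMS)
        error("parameter vector must have length %d", N_PARMS);
    SEXP out = PROTECT(allocVector(REALSXP, neq));
    ppi_rhs_core(REAL(p), asReal(t), REAL(y), REAL(out), neq);
    UNPROTECT(1);
    return out;
}
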